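#' Merged hit coverage of a query genome
#'
#' Fraction of the query genome covered by the union of alignment-hit
#' intervals. Used for phage detection in isolate genomes, database-match
#' calls on candidate-prophage regions, and cognate-genome identification.
#'
#' @param hits data.frame with `qstart`, `qend` columns (1-based inclusive
#'   query coordinates; reversed hits must be normalized so
#'   `qstart <= qend`).
#' @param query_len query genome length in nt (positive).
#' @return A single fraction in `[0, 1]`.
#' @examples
#' merged_coverage_fraction(data.frame(qstart = c(1, 41), qend = c(50, 100)), 100)
#' @export
merged_coverage_fraction <- function(hits, query_len) {
  query_len <- as.integer(query_len)
  if (is.na(query_len) || query_len < 1L) stop("query_len must be positive")
  hits <- as.data.frame(hits)
  if (!nrow(hits)) return(0)
  if (any(hits$qstart > hits$qend)) stop("hit with qstart > qend")
  if (any(hits$qstart < 1L) || any(hits$qend > query_len)) {
    stop("hit interval beyond the query genome")
  }
  ir <- IRanges::reduce(IRanges::IRanges(as.integer(hits$qstart),
                                         as.integer(hits$qend)))
  sum(IRanges::width(ir)) / query_len
}

#' Threshold a coverage or breadth fraction for detection
#'
#' Applies the detection rule matching the analysis context, all boundaries
#' inclusive: `"metagenome"` calls a phage detected in a bulk sample at
#' read breadth >= 0.75; `"isolate"` calls it present in an isolate genome
#' at hit coverage >= 0.95; `"cp_db"` calls a candidate-prophage region a
#' database match at >= 0.30; `"cognate"` defines a cognate database genome
#' at >= 0.95.
#'
#' @param fraction coverage or breadth fraction in `[0, 1]`.
#' @param mode one of `"metagenome"`, `"isolate"`, `"cp_db"`, `"cognate"`.
#' @param thr thresholds from [dgr_thresholds()].
#' @return Logical.
#' @export
detect_phage <- function(fraction, mode = c("metagenome", "isolate",
                                            "cp_db", "cognate"),
                         thr = dgr_thresholds()) {
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || any(fraction < 0) || any(fraction > 1)) {
    stop("fraction must lie in [0, 1]")
  }
  cut <- switch(mode,
                metagenome = thr$metagenome_detect_breadth,
                isolate = thr$isolate_detect_cov,
                cp_db = thr$cp_db_match_cov,
                cognate = thr$cognate_cov)
  fraction >= cut
}

#' Match CRISPR spacers against a phage genome
#'
#' Scans both strands of the genome for gap-free matches of each spacer,
#' allowing up to `floor((1 - spacer_identity_min) * length)` mismatches so
#' that every reported match has identity at or above the threshold over
#' the full spacer length. A spacer-protospacer match ties a phage to the
#' bacterial host whose CRISPR array holds the spacer. Spacers containing N
#' are skipped with a warning.
#'
#' @param spacers named character vector or `DNAStringSet` of spacers
#'   (each at least 20 nt).
#' @param genome phage genome sequence.
#' @param thr thresholds from [dgr_thresholds()].
#' @return A data.frame ordered by genome position then strand (`+` before
#'   `-`): `spacer_id`, `position` (1-based match start on the plus
#'   strand), `strand`, `mismatches`, `identity`.
#' @export
match_spacers <- function(spacers, genome, thr = dgr_thresholds()) {
  if (methods::is(spacers, "DNAStringSet") ||
      methods::is(spacers, "XStringSet")) {
    spacers <- setNames(as.character(spacers), names(spacers))
  }
  if (is.null(names(spacers)) || any(!nzchar(names(spacers)))) {
    stop("spacers must be named")
  }
  seq <- as_genome_seq(genome)
  subject <- Biostrings::DNAString(seq)
  rows <- list()
  for (id in names(spacers)) {
    sp <- toupper(spacers[[id]])
    len <- nchar(sp)
    if (len < 20L) stop("spacer '", id, "' shorter than 20 nt")
    if (grepl("N", sp, fixed = TRUE)) {
      warning("spacer '", id, "' contains N; skipped", call. = FALSE)
      next
    }
    max_mm <- floor((1 - thr$spacer_identity_min) * len)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") sp else revcomp_chr(sp)
      m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mm,
                                    with.indels = FALSE)
      if (!length(m)) next
      mm <- Biostrings::neditAt(Biostrings::DNAString(pat), subject,
                                at = BiocGenerics::start(m))
      rows[[length(rows) + 1L]] <- data.frame(
        spacer_id = id, position = BiocGenerics::start(m), strand = strand,
        mismatches = as.integer(mm), identity = 1 - mm / len)
    }
  }
  if (!length(rows)) {
    return(data.frame(spacer_id = character(), position = integer(),
                      strand = character(), mismatches = integer(),
                      identity = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position, match(out$strand, c("+", "-")),
                   out$spacer_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy species-level clustering of phage genomes
#'
#' Clusters genomes into species-level units by the standard viral
#' criterion: average nucleotide identity (ANI) at or above 95 percent with
#' alignment coverage of the shorter genome (tcov) at or above 85 percent.
#' Genomes are sorted by decreasing length (ties by id); each genome joins
#' the earliest-founded cluster whose representative satisfies both
#' thresholds with it, else founds its own cluster.
#'
#' @param genomes data.frame with `id` and `length` columns.
#' @param pairwise data.frame with `id_a`, `id_b`, `ani` (percent) and
#'   `tcov` (percent, coverage of the shorter genome). Asymmetric tables
#'   are symmetrized by the maximum.
#' @param thr thresholds from [dgr_thresholds()].
#' @return A data.frame with `id`, `cluster` (integer), `representative`.
#' @export
greedy_species_clusters <- function(genomes, pairwise,
                                    thr = dgr_thresholds()) {
  genomes <- as.data.frame(genomes)
  pairwise <- as.data.frame(pairwise)
  if (nrow(pairwise)) {
    unknown <- setdiff(unique(c(pairwise$id_a, pairwise$id_b)), genomes$id)
    if (length(unknown)) {
      stop("pairwise table names unknown genome(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ani <- new.env(parent = emptyenv())
  tcov <- new.env(parent = emptyenv())
  if (nrow(pairwise)) {
    for (i in seq_len(nrow(pairwise))) {
      kk <- key(pairwise$id_a[i], pairwise$id_b[i])
      ani[[kk]] <- max(pairwise$ani[i], mget(kk, ani, ifnotfound = -Inf)[[1]])
      tcov[[kk]] <- max(pairwise$tcov[i], mget(kk, tcov, ifnotfound = -Inf)[[1]])
    }
  }
  o <- order(-genomes$length, genomes$id)
  ids <- genomes$id[o]
  rep_ids <- character(0)
  assignment <- setNames(character(length(ids)), ids)
  for (id in ids) {
    joined <- FALSE
    for (r in rep_ids) {
      kk <- key(id, r)
      a <- mget(kk, ani, ifnotfound = -Inf)[[1]]
      tc <- mget(kk, tcov, ifnotfound = -Inf)[[1]]
      if (a >= thr$ani_min && tc >= thr$tcov_min) {
        assignment[[id]] <- r
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      rep_ids <- c(rep_ids, id)
      assignment[[id]] <- id
    }
  }
  data.frame(id = names(assignment),
             cluster = match(unname(assignment), rep_ids),
             representative = unname(assignment), row.names = NULL)
}
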