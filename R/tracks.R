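#' Per-window nucleotide content of a genome
#'
#' Computes, for every sliding window, the fraction of A, C, G and T among
#' the non-N positions of the window. Deviations of these fractions from the
#' contig-wide background are one of the five lines of evidence for an
#' integrated prophage, whose nucleotide composition often differs from its
#' host's.
#'
#' @param genome a nucleotide sequence (character scalar, `DNAString`, or
#'   single-record `DNAStringSet`) over the alphabet A/C/G/T/N.
#' @param spec a [window_spec()]; bacterial contigs conventionally use
#'   [bacterial_window_spec()].
#' @return A data.frame with columns `start`, `end`, `A`, `C`, `G`, `T`.
#'   Windows consisting entirely of N have all four fractions `NA`.
#' @examples
#' nucleotide_content_track(strrep("ACGT", 100), window_spec(100, 50, 25))
#' @export
nucleotide_content_track <- function(genome, spec = bacterial_window_spec()) {
  seq <- as_genome_seq(genome)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  check_nucleotides(chars)
  windows <- enumerate_windows(length(chars), spec)
  out <- windows
  counts <- lapply(c("A", "C", "G", "T"), function(b) {
    window_sum(chars == b, windows)
  })
  informative <- window_sum(chars != "N", windows)
  for (i in seq_along(counts)) {
    v <- counts[[i]] / informative
    v[informative == 0] <- NA_real_
    out[[c("A", "C", "G", "T")[i]]] <- v
  }
  out
}

#' Per-window ORF organization statistics
#'
#' Prophage regions tend to encode shorter genes separated by shorter
#' intergenic gaps, and consecutive prophage genes rarely switch coding
#' strand. This track quantifies those contrasts per window. An ORF belongs
#' to the window containing its midpoint; gap and strand-switch statistics
#' are computed between consecutive (by start) ORFs assigned to the window.
#'
#' @param orfs data.frame with columns `start`, `end` (1-based inclusive) and
#'   `strand` (`"+"` or `"-"`); a `contig_id` column, if present, must be
#'   single-valued.
#' @param contig_len contig length in nt.
#' @param spec a [window_spec()].
#' @return A data.frame with columns `start`, `end`, `median_orf_len`,
#'   `median_gap`, `strand_switches`, `coding_density`. Windows with fewer
#'   than two assigned ORFs have `NA` medians and switch counts.
#' @export
orf_organization_track <- function(orfs, contig_len,
                                   spec = bacterial_window_spec()) {
  contig_len <- as.integer(contig_len)
  orfs <- validate_orfs(orfs, contig_len)
  windows <- enumerate_windows(contig_len, spec)
  out <- windows
  n_win <- nrow(windows)
  out$median_orf_len <- NA_real_
  out$median_gap <- NA_real_
  out$strand_switches <- NA_real_

  ## coding density from per-position coverage by any ORF
  cov <- rep(0L, contig_len)
  if (nrow(orfs)) {
    ir <- IRanges::reduce(IRanges::IRanges(orfs$start, orfs$end))
    for (k in seq_along(ir)) {
      cov[IRanges::start(ir)[k]:IRanges::end(ir)[k]] <- 1L
    }
  }
  out$coding_density <- window_mean(cov, windows)

  if (nrow(orfs)) {
    orfs <- orfs[order(orfs$start, orfs$end), , drop = FALSE]
    mids <- floor((orfs$start + orfs$end) / 2)
    lens <- orfs$end - orfs$start + 1L
    for (w in seq_len(n_win)) {
      in_w <- which(mids >= windows$start[w] & mids <= windows$end[w])
      if (length(in_w) < 2L) next
      out$median_orf_len[w] <- stats::median(lens[in_w])
      gaps <- orfs$start[in_w][-1L] - orfs$end[in_w][-length(in_w)] - 1L
      out$median_gap[w] <- stats::median(gaps)
      s <- orfs$strand[in_w]
      out$strand_switches[w] <- sum(s[-1L] != s[-length(s)])
    }
  }
  out
}

validate_orfs <- function(orfs, contig_len = NULL) {
  orfs <- as.data.frame(orfs)
  need <- c("start", "end", "strand")
  miss <- setdiff(need, names(orfs))
  if (length(miss)) stop("orfs lack column(s): ", paste(miss, collapse = ", "))
  orfs$start <- as.integer(orfs$start); orfs$end <- as.integer(orfs$end)
  if (nrow(orfs)) {
    if (any(orfs$start > orfs$end)) stop("ORF with start > end")
    if (any(!(orfs$strand %in% c("+", "-")))) {
      stop("ORF strand must be '+' or '-'")
    }
    if (!is.null(contig_len) &&
        (any(orfs$start < 1L) || any(orfs$end > contig_len))) {
      stop("ORF outside contig bounds [1, ", contig_len, "]")
    }
  }
  orfs
}

#' Per-window read-coverage depth and breadth
#'
#' Reads recruited from virus-like-particle metagenomes pile up over
#' prophage regions; this computes, per sliding window, the mean coverage
#' depth and the breadth (fraction of positions with depth strictly greater
#' than zero).
#'
#' @param depth integer vector of per-position read depth, one entry per
#'   contig position.
#' @param spec a [window_spec()].
#' @param contig_len optional expected contig length; an error is raised if
#'   `length(depth)` differs.
#' @return A data.frame with columns `start`, `end`, `mean_depth`, `breadth`.
#' @export
depth_breadth_tracks <- function(depth, spec = bacterial_window_spec(),
                                 contig_len = NULL) {
  depth <- as.numeric(depth)
  if (any(is.na(depth)) || any(depth < 0)) {
    stop("depth must be nonnegative and free of NA")
  }
  if (!is.null(contig_len) && length(depth) != as.integer(contig_len)) {
    stop("depth profile length (", length(depth),
         ") does not match contig length (", contig_len, ")")
  }
  windows <- enumerate_windows(length(depth), spec)
  out <- windows
  out$mean_depth <- window_mean(depth, windows)
  out$breadth <- window_mean(depth > 0, windows)
  out
}
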