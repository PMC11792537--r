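## Genome self-alignment for DGR repeat discovery.
##
## The production path (find_repeat_alignments) seeds on exact shared words
## and extends each seed cluster by banded affine-gap local alignment; the
## reference path (exhaustive_repeat_alignments) enumerates optimal local
## alignments over the full dynamic-programming matrix and exists to
## validate the seeded search on small inputs. Both share scoring
## (match +2, mismatch -3, gap open -5, gap extend -2) and postprocessing.

default_scoring <- function() {
  list(match = 2L, mismatch = 3L, gap_open = 5L, gap_ext = 2L)
}

revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
}

## integer codes of all k-mers; NA where the word contains N
encode_words <- function(chars, k) {
  n <- length(chars)
  if (n < k) return(numeric(0))
  code <- c(A = 0, C = 1, G = 2, T = 3, N = NA_real_)[chars]
  val <- numeric(n - k + 1L)
  for (t in 0:(k - 1L)) {
    val <- val * 4 + code[(1L + t):(n - k + 1L + t)]
  }
  val
}

## seed pairs between two word-code vectors; returns matrix cols (i, j)
seed_pairs <- function(codes1, codes2 = NULL, max_occ = 100L) {
  self <- is.null(codes2)
  if (self) codes2 <- codes1
  ok1 <- which(!is.na(codes1)); ok2 <- which(!is.na(codes2))
  sp1 <- split(ok1, codes1[ok1])
  sp2 <- if (self) sp1 else split(ok2, codes2[ok2])
  common <- intersect(names(sp1), names(sp2))
  out <- vector("list", length(common))
  for (ci in seq_along(common)) {
    p1 <- sp1[[common[ci]]]; p2 <- sp2[[common[ci]]]
    if (length(p1) > max_occ || length(p2) > max_occ) next
    if (self) {
      if (length(p1) < 2L) next
      cmb <- utils::combn(p1, 2L)
      out[[ci]] <- cbind(cmb[1L, ], cmb[2L, ])
    } else {
      out[[ci]] <- cbind(rep(p1, each = length(p2)),
                         rep(p2, times = length(p1)))
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(matrix(integer(0), ncol = 2L))
  do.call(rbind, out)
}

## cluster seed pairs on nearby diagonals into extension candidates
cluster_seeds <- function(pairs, max_diag_drift = 16L, max_gap = 200L) {
  if (!nrow(pairs)) return(list())
  d <- pairs[, 2L] - pairs[, 1L]
  o <- order(d, pairs[, 1L])
  pairs <- pairs[o, , drop = FALSE]; d <- d[o]
  brk <- c(TRUE, diff(d) > max_diag_drift |
             diff(pairs[, 1L]) > max_gap | diff(pairs[, 1L]) < -max_gap)
  grp <- cumsum(brk)
  lapply(split(seq_len(nrow(pairs)), grp), function(idx) {
    list(i1 = min(pairs[idx, 1L]), i2 = max(pairs[idx, 1L]),
         j1 = min(pairs[idx, 2L]), j2 = max(pairs[idx, 2L]),
         d_lo = min(d[idx]), d_hi = max(d[idx]))
  })
}

aln_stats <- function(aln1, aln2) {
  c1 <- strsplit(aln1, "", fixed = TRUE)[[1L]]
  c2 <- strsplit(aln2, "", fixed = TRUE)[[1L]]
  g1 <- c1 == "-"; g2 <- c2 == "-"
  sub_col <- !g1 & !g2
  ident <- sum(sub_col & c1 == c2)
  mism <- sum(sub_col & c1 != c2)
  list(aln_len = length(c1), identities = ident, mismatches = mism,
       gaps_1 = sum(g1), gaps_2 = sum(g2),
       pid = 100 * ident / length(c1),
       mismatch_cols = which(sub_col & c1 != c2))
}

new_repeat_alignment <- function(contig_id, s1, e1, s2, e2, orientation,
                                 aln1, aln2, score) {
  st <- aln_stats(aln1, aln2)
  structure(c(list(
    interval_1 = interval(contig_id, s1, e1),
    interval_2 = interval(contig_id, s2, e2),
    orientation = orientation, aln1 = aln1, aln2 = aln2, score = score), st),
    class = "repeat_alignment")
}

#' @export
print.repeat_alignment <- function(x, ...) {
  cat(sprintf(
    "<repeat_alignment> %s:%d-%d vs %d-%d (%s) len=%d pid=%.1f mism=%d\n",
    x$interval_1$contig_id, x$interval_1$start, x$interval_1$end,
    x$interval_2$start, x$interval_2$end, x$orientation,
    x$aln_len, x$pid, x$mismatches))
  invisible(x)
}

## swap sides of an opposite-orientation alignment (revcomp both rows)
revcomp_aln <- function(a) chartr("ACGTN-", "TGCAN-",
                                  paste(rev(strsplit(a, "", fixed = TRUE)[[1L]]),
                                        collapse = ""))

## shared postprocessing: same-strand hits come with seq1/seq2 both in
## genome coordinates; opposite hits with seq2 in reverse-complement
## coordinates. Canonicalizes so interval_1 starts first, drops
## self-identities and mirror duplicates, applies length/identity gates.
postprocess_hits <- function(raw, contig_id, glen, thr, min_score) {
  alns <- list()
  seen <- character(0)
  for (h in raw) {
    if (h$score < min_score) next
    if (h$orientation == "same") {
      s1 <- h$start1; e1 <- h$end1; s2 <- h$start2; e2 <- h$end2
      a1 <- h$aln1; a2 <- h$aln2
      if (s1 == s2 && e1 == e2) next
      if (s1 > s2) {
        tmp <- s1; s1 <- s2; s2 <- tmp; tmp <- e1; e1 <- e2; e2 <- tmp
        tmp <- a1; a1 <- a2; a2 <- tmp
      }
    } else {
      s1 <- h$start1; e1 <- h$end1
      s2 <- glen - h$end2 + 1L; e2 <- glen - h$start2 + 1L
      a1 <- h$aln1; a2 <- h$aln2
      if (s1 == s2 && e1 == e2) next  # palindromic self-match
      if (s1 > s2) {
        tmp <- s1; s1 <- s2; s2 <- tmp; tmp <- e1; e1 <- e2; e2 <- tmp
        na1 <- revcomp_aln(a2); na2 <- revcomp_aln(a1)
        a1 <- na1; a2 <- na2
      }
    }
    key <- paste(s1, e1, s2, e2, h$orientation, sep = ":")
    if (key %in% seen) next
    seen <- c(seen, key)
    aln <- new_repeat_alignment(contig_id, s1, e1, s2, e2, h$orientation,
                                a1, a2, h$score)
    if (aln$aln_len < thr$dgr_min_aln_len) next
    if (aln$pid < thr$dgr_min_pid) next
    alns[[length(alns) + 1L]] <- aln
  }
  if (!length(alns)) return(alns)
  o <- order(vapply(alns, function(a) a$interval_1$start, numeric(1)),
             vapply(alns, function(a) a$interval_2$start, numeric(1)))
  alns[o]
}

## greedy dedup in matrix coordinates, mirroring the rectangle masking of
## the exhaustive path: best score first, ties toward the smallest end
## cell; a candidate is dropped only when its bounding box intersects an
## accepted alignment's bounding box in BOTH dimensions (the same locus
## pair found twice), so one repeat aligned to several partners keeps one
## alignment per partner.
greedy_mask_dedup <- function(hits) {
  if (!length(hits)) return(hits)
  o <- order(-vapply(hits, function(h) h$score, numeric(1)),
             vapply(hits, function(h) h$end1, numeric(1)),
             vapply(hits, function(h) h$end2, numeric(1)))
  hits <- hits[o]
  used <- matrix(numeric(0), ncol = 4L)
  keep <- logical(length(hits))
  for (k in seq_along(hits)) {
    h <- hits[[k]]
    clash <- nrow(used) > 0 &&
      any(used[, 1L] <= h$end1 & used[, 2L] >= h$start1 &
            used[, 3L] <= h$end2 & used[, 4L] >= h$start2)
    if (clash) next
    keep[k] <- TRUE
    used <- rbind(used, c(h$start1, h$end1, h$start2, h$end2))
  }
  hits[keep]
}

#' Find repeat alignments by genome self-comparison
#'
#' Compares a genome to itself (both strands) to locate repeated segments,
#' the raw material of DGR template/variable repeat detection. Exact shared
#' words of length `thr$seed_word` seed the search; each seed cluster is
#' extended by local alignment in a diagonal band, the trivial self-identity
#' and mirror duplicates are removed, alignments shorter than
#' `thr$dgr_min_aln_len` columns or below `thr$dgr_min_pid` percent identity
#' are discarded, and overlapping alignments are reduced to the
#' highest-scoring representative.
#'
#' @param genome nucleotide sequence (character, `DNAString`, or one-record
#'   `DNAStringSet`); its name, if any, is used as the contig id.
#' @param thr thresholds from [dgr_thresholds()].
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_ext`
#'   (penalties positive).
#' @param min_score minimum local-alignment score retained (default 40).
#' @param band_width half-width, in diagonals, of the extension band around
#'   a seed cluster (default 100).
#' @param pad nucleotides of context extracted on each side of a seed
#'   cluster before extension (default 250).
#' @return A list of `repeat_alignment` objects sorted by coordinates, each
#'   with genome intervals (1-based inclusive), orientation (`"same"` or
#'   `"opposite"`), aligned strings, alignment length, identities,
#'   mismatches, per-side gap counts and percent identity.
#' @seealso [exhaustive_repeat_alignments()] for the reference
#'   implementation, [classify_dgr_pair()] for DGR classification.
#' @export
find_repeat_alignments <- function(genome, thr = dgr_thresholds(),
                                   scoring = default_scoring(),
                                   min_score = 40L, band_width = 100L,
                                   pad = 250L) {
  seq <- as_genome_seq(genome)
  contig_id <- names(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  check_nucleotides(chars)
  glen <- length(chars)
  if (glen < thr$dgr_min_aln_len) {
    stop("genome shorter than the minimum repeat alignment length")
  }
  k <- as.integer(thr$seed_word)
  codes_f <- encode_words(chars, k)
  rc <- revcomp_chr(seq)
  codes_r <- encode_words(strsplit(rc, "", fixed = TRUE)[[1L]], k)

  extend <- function(cl, seq2, orientation) {
    a1 <- max(1L, cl$i1 - pad); a2 <- min(glen, cl$i2 + k - 1L + pad)
    b1 <- max(1L, cl$j1 - pad); b2 <- min(glen, cl$j2 + k - 1L + pad)
    sub1 <- substr(seq, a1, a2)
    sub2 <- substr(seq2, b1, b2)
    shift <- b1 - a1
    band_lo <- cl$d_lo - shift - band_width
    band_hi <- cl$d_hi - shift + band_width
    forbid <- if (orientation == "same") -shift else 0L
    r <- cpp_local_align(sub1, sub2, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_ext,
                         band_lo, band_hi, forbid,
                         TRUE, orientation == "same")
    if (r$score <= 0) return(NULL)
    list(score = r$score,
         start1 = a1 + r$start1 - 1L, end1 = a1 + r$end1 - 1L,
         start2 = b1 + r$start2 - 1L, end2 = b1 + r$end2 - 1L,
         aln1 = r$aln1, aln2 = r$aln2, orientation = orientation)
  }

  raw_same <- list(); raw_opp <- list()
  for (cl in cluster_seeds(seed_pairs(codes_f))) {
    h <- extend(cl, seq, "same")
    if (!is.null(h)) raw_same[[length(raw_same) + 1L]] <- h
  }
  for (cl in cluster_seeds(seed_pairs(codes_f, codes_r))) {
    h <- extend(cl, rc, "opposite")
    if (!is.null(h)) raw_opp[[length(raw_opp) + 1L]] <- h
  }
  ## each orientation is an independent alignment matrix; mask separately
  raw <- c(greedy_mask_dedup(raw_same), greedy_mask_dedup(raw_opp))
  postprocess_hits(raw, contig_id, glen, thr, min_score)
}

#' Exhaustive repeat-alignment reference
#'
#' Reference implementation of the genome self-comparison: enumerates
#' optimal local alignments over the full dynamic-programming matrix (same
#' scoring and acceptance gates as [find_repeat_alignments()]), masking each
#' accepted alignment's rows and columns before searching again. Quadratic
#' in genome length; intended for validation on genomes of a few kb.
#'
#' @inheritParams find_repeat_alignments
#' @param max_hits maximum alignments enumerated per strand (default 50).
#' @return As [find_repeat_alignments()].
#' @export
exhaustive_repeat_alignments <- function(genome, thr = dgr_thresholds(),
                                         scoring = default_scoring(),
                                         min_score = 40L, max_hits = 50L) {
  seq <- as_genome_seq(genome)
  contig_id <- names(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  check_nucleotides(chars)
  glen <- length(chars)
  if (glen < thr$dgr_min_aln_len) {
    stop("genome shorter than the minimum repeat alignment length")
  }
  rc <- revcomp_chr(seq)
  raw <- list()
  fwd <- cpp_sw_enumerate(seq, seq, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_ext,
                          min_score, TRUE, max_hits)
  for (h in fwd) { h$orientation <- "same"; raw[[length(raw) + 1L]] <- h }
  rvs <- cpp_sw_enumerate(seq, rc, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_ext,
                          min_score, FALSE, max_hits)
  for (h in rvs) { h$orientation <- "opposite"; raw[[length(raw) + 1L]] <- h }
  postprocess_hits(raw, contig_id, glen, thr, min_score)
}
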