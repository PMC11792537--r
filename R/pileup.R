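#' Per-position nucleotide variation from a read pileup
#'
#' For every reference position with at least one mapped base, the variation
#' is the proportion of read nucleotides different from the most frequent
#' one; positions with zero depth are missing. Only A/C/G/T base calls are
#' counted. This is the single-sample, single-time-point analogue of MSA
#' column variation and captures DGR activity in the sequenced population.
#'
#' @param pileup data.frame (or matrix) with columns `A`, `C`, `G`, `T` of
#'   per-position base counts, ordered by position.
#' @return A numeric vector of per-position variation (`NA` at depth 0).
#' @seealso [variation_track()] for the windowed companion track.
#' @export
pileup_variation <- function(pileup) {
  counts <- as.matrix(as.data.frame(pileup)[, c("A", "C", "G", "T")])
  if (any(counts < 0)) stop("negative base counts in pileup")
  depth <- rowSums(counts)
  top <- apply(counts, 1L, max)
  out <- 1 - top / depth
  out[depth == 0] <- NA_real_
  unname(out)
}

#' Pileup sample-inclusion rule
#'
#' A sample is analyzed for DGR activity only when its coverage is deep and
#' wide enough to make per-position variation meaningful: depth at least
#' `thr$pileup_min_depth` along at least `thr$pileup_min_breadth` of the
#' genome length (both boundaries inclusive).
#'
#' @param pileup data.frame with `A`, `C`, `G`, `T` count columns, one row
#'   per genome position.
#' @param thr thresholds from [dgr_thresholds()].
#' @return A list with `breadth` (fraction of positions at or above the
#'   depth floor) and `include` (logical).
#' @export
sample_inclusion <- function(pileup, thr = dgr_thresholds()) {
  counts <- as.matrix(as.data.frame(pileup)[, c("A", "C", "G", "T")])
  depth <- rowSums(counts)
  breadth <- mean(depth >= thr$pileup_min_depth)
  list(breadth = breadth, include = breadth >= thr$pileup_min_breadth)
}

#' Call DGR activity at variable repeats from a variation track
#'
#' A variable repeat is called active when the mean windowed variation over
#' the windows intersecting it exceeds the track median by more than
#' `k` median absolute deviations. The effect size reported is
#' (VR mean - median) / MAD. The rule formalizes the visual criterion of a
#' variation spike standing clear of the genome-wide background.
#'
#' @param track a windowed variation track from [variation_track()].
#' @param vrs list of VR intervals (each with `start`, `end`), or a
#'   data.frame with `start`/`end` columns.
#' @param k MAD multiplier (default 5).
#' @param genome_len optional genome length used to validate VR bounds.
#' @return A data.frame with one row per VR: `start`, `end`, `vr_mean`,
#'   `track_median`, `track_mad`, `effect_size`, `active`.
#' @export
vr_activity_call <- function(track, vrs, k = 5, genome_len = NULL) {
  if (is.data.frame(vrs)) {
    vrs <- lapply(seq_len(nrow(vrs)), function(i) as.list(vrs[i, ]))
  }
  med <- stats::median(track$variation, na.rm = TRUE)
  scale <- stats::mad(track$variation, na.rm = TRUE)
  rows <- lapply(vrs, function(vr) {
    s <- as.integer(vr$start); e <- as.integer(vr$end)
    if (!is.null(genome_len) && (s < 1L || e > genome_len)) {
      stop("VR interval outside the genome")
    }
    hit <- track$start <= e & track$end >= s
    vr_mean <- mean(track$variation[hit], na.rm = TRUE)
    delta <- vr_mean - med
    effect <- if (scale > 0) delta / scale else if (delta > 0) Inf else 0
    data.frame(start = s, end = e, vr_mean = vr_mean, track_median = med,
               track_mad = scale, effect_size = effect,
               active = is.finite(vr_mean) && delta > k * scale)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
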