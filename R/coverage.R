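#' Virome-sample contamination filter
#'
#' A virus-like-particle (VLP) metagenome sample whose reads cover more than
#' a quarter of the cumulative length of a bacterial strain assembly is
#' likely contaminated with bacterial DNA and is excluded from prophage
#' read-recruitment evidence. The boundary is strict: a sample at exactly
#' the threshold breadth is kept.
#'
#' @param depths named list of per-contig depth vectors for one sample over
#'   all contigs of one strain (names are contig ids).
#' @param contig_lengths optional named integer vector of expected contig
#'   lengths; contigs missing from `depths` are an error.
#' @param thr thresholds from [dgr_thresholds()].
#' @return A list with `breadth` (cumulative fraction of positions with
#'   depth > 0) and `exclude` (logical).
#' @examples
#' contamination_filter(list(c1 = c(0, 0, 3, 9), c2 = rep(0, 4)))
#' @export
contamination_filter <- function(depths, contig_lengths = NULL,
                                 thr = dgr_thresholds()) {
  if (!is.list(depths) || !length(depths)) {
    stop("'depths' must be a nonempty list of per-contig depth vectors")
  }
  if (!is.null(contig_lengths)) {
    miss <- setdiff(names(contig_lengths), names(depths))
    if (length(miss)) {
      stop("missing depth profile for contig(s): ", paste(miss, collapse = ", "))
    }
    for (id in names(contig_lengths)) {
      if (length(depths[[id]]) != contig_lengths[[id]]) {
        stop("depth profile length mismatch for contig ", id)
      }
    }
  }
  covered <- sum(vapply(depths, function(d) sum(d > 0), numeric(1)))
  total <- sum(vapply(depths, length, numeric(1)))
  breadth <- covered / total
  list(breadth = breadth, exclude = breadth > thr$contamination_breadth_max)
}

#' Prophage induction coverage ratio
#'
#' Ratio between the mean read depth over a prophage region and the mean
#' depth over the remainder of the bacterial contig carrying it. Values far
#' above 1 in VLP sequencing indicate that the prophage was actively
#' replicating (induced) when the sample was taken.
#'
#' @param depth per-position depth vector for the whole contig.
#' @param prophage list or data.frame row with `start` and `end` (1-based
#'   inclusive) of the prophage region; must be strictly inside the contig.
#' @return A list with `ratio`, `mean_inside`, `mean_outside`, and
#'   `infinite` (TRUE when the outside mean is zero, in which case `ratio`
#'   is `Inf`).
#' @export
coverage_ratio <- function(depth, prophage) {
  depth <- as.numeric(depth)
  n <- length(depth)
  s <- as.integer(prophage$start); e <- as.integer(prophage$end)
  if (is.na(s) || is.na(e) || s < 1L || e > n || s > e) {
    stop("prophage interval must lie within the contig")
  }
  if (s == 1L && e == n) {
    stop("prophage region covers the whole contig; no outside positions")
  }
  inside <- mean(depth[s:e])
  outside <- mean(depth[-(s:e)])
  if (outside == 0) {
    list(ratio = Inf, mean_inside = inside, mean_outside = 0, infinite = TRUE)
  } else {
    list(ratio = inside / outside, mean_inside = inside,
         mean_outside = outside, infinite = FALSE)
  }
}

#' Call candidate prophage regions from evidence tracks
#'
#' Combines any number of per-window evidence tracks into candidate-region
#' calls. Each signal is converted to a robust z-score against the whole
#' contig (median/MAD), multiplied by its expected direction (+1 when high
#' values indicate a prophage, e.g. VLP depth; -1 when low values do, e.g.
#' median ORF length), summed across the signals available in a window, and
#' thresholded. Windows over the cutoff are merged when adjacent or
#' separated by at most `max_gap_windows`; merged regions shorter than
#' `min_region_len` are dropped.
#'
#' This caller is an explicit algorithmic stand-in for combining the five
#' lines of evidence by eye; its defaults are conservative for typical
#' prophage lengths (roughly 30-60 kb).
#'
#' @param tracks data.frame with `start`, `end` and one numeric column per
#'   signal (all tracks must be on the same window grid; join columns from
#'   the individual track functions beforehand).
#' @param directions named numeric vector of +1/-1 per signal column;
#'   signals absent from `directions` default to +1.
#' @param cutoff summed-z cutoff (default 3.0).
#' @param min_region_len minimum merged region length in nt (default 15000).
#' @param max_gap_windows windows over the cutoff are merged across gaps of
#'   at most this many sub-threshold windows (default 1).
#' @return A data.frame of regions with columns `start`, `end`, `n_windows`,
#'   `max_score`, `mean_score`.
#' @export
call_candidate_regions <- function(tracks, directions = NULL, cutoff = 3.0,
                                   min_region_len = 15000L,
                                   max_gap_windows = 1L) {
  if (!all(c("start", "end") %in% names(tracks))) {
    stop("tracks must carry 'start' and 'end' window columns")
  }
  sig_cols <- setdiff(names(tracks), c("start", "end", "contig_id"))
  if (!length(sig_cols)) stop("no signal columns in tracks")
  n_win <- nrow(tracks)
  zsum <- rep(0, n_win)
  for (sc in sig_cols) {
    v <- as.numeric(tracks[[sc]])
    dir <- if (!is.null(directions) && sc %in% names(directions)) {
      directions[[sc]]
    } else 1
    med <- stats::median(v, na.rm = TRUE)
    scale <- stats::mad(v, na.rm = TRUE)
    if (!is.finite(med) || !is.finite(scale) || scale == 0) next
    z <- dir * (v - med) / scale
    z[is.na(z)] <- 0
    zsum <- zsum + z
  }
  over <- zsum > cutoff
  regions <- data.frame(start = integer(), end = integer(),
                        n_windows = integer(), max_score = numeric(),
                        mean_score = numeric())
  if (!any(over)) return(regions)
  idx <- which(over)
  grp <- cumsum(c(1L, diff(idx) > (max_gap_windows + 1L)))
  for (g in unique(grp)) {
    members <- idx[grp == g]
    lo <- min(members); hi <- max(members)
    reg_start <- tracks$start[lo]; reg_end <- tracks$end[hi]
    if (reg_end - reg_start + 1L < min_region_len) next
    span <- lo:hi
    regions <- rbind(regions, data.frame(
      start = reg_start, end = reg_end, n_windows = length(members),
      max_score = max(zsum[span]), mean_score = mean(zsum[span])))
  }
  rownames(regions) <- NULL
  regions
}

#' Call transposable-phage termini from split-read junctions
#'
#' A transposable (Mu-like) phage packages its genome together with variable
#' host flanks; split-read alignments therefore link many distant host loci
#' to two specific nucleotides at the prophage borders. Junction positions
#' are clustered (positions closer than `min_separation` collapse into one
#' cluster) and the two best-supported clusters are reported as the left and
#' right termini. The position reported for a cluster is its modal junction
#' position, with its own count as the support; ties break toward the
#' smaller coordinate.
#'
#' @param junctions data.frame with a `position` column and optionally a
#'   `count` column (absent counts default to 1 per row).
#' @param min_separation minimum distance, in nt, between the two reported
#'   termini (default 100).
#' @return A list with `left`, `right` (positions, `right` may be `NA` when
#'   only one cluster exists), `support` (length-2 counts), `total`
#'   (total junction alignments) and `explained_fraction`.
#' @export
call_transposable_termini <- function(junctions, min_separation = 100L) {
  junctions <- as.data.frame(junctions)
  if (!nrow(junctions)) stop("no junction records supplied")
  if (!("position" %in% names(junctions))) {
    stop("junctions must carry a 'position' column")
  }
  cnt <- if ("count" %in% names(junctions)) {
    as.numeric(junctions$count)
  } else rep(1, nrow(junctions))
  tab <- tapply(cnt, as.integer(junctions$position), sum)
  pos <- as.integer(names(tab)); support <- as.numeric(tab)
  o <- order(pos)
  pos <- pos[o]; support <- support[o]
  ## cluster positions separated by < min_separation
  grp <- cumsum(c(1L, diff(pos) >= min_separation))
  cl_pos <- integer(0)
  cl_sup <- cl_tot <- numeric(0)
  for (g in unique(grp)) {
    m <- grp == g
    p <- pos[m]; s <- support[m]
    best <- which(s == max(s))[1L]          # ties toward smaller coordinate
    cl_pos <- c(cl_pos, p[best])
    cl_sup <- c(cl_sup, s[best])
    cl_tot <- c(cl_tot, sum(s))
  }
  o <- order(-cl_sup, cl_pos)
  total <- sum(support)
  if (length(cl_pos) == 1L) {
    return(list(left = cl_pos[1L], right = NA_integer_,
                support = c(cl_sup[1L], NA_real_), total = total,
                explained_fraction = cl_tot[1L] / total))
  }
  top2 <- o[1:2]
  lr <- order(cl_pos[top2])
  top2 <- top2[lr]
  list(left = cl_pos[top2[1L]], right = cl_pos[top2[2L]],
       support = cl_sup[top2], total = total,
       explained_fraction = sum(cl_tot[top2]) / total)
}
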