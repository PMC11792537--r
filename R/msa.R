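#' Per-column variation and conservation of an MSA, in reference coordinates
#'
#' Summarizes a multiple sequence alignment of cognate genomes column by
#' column. One aligned sequence is designated the reference; columns where
#' the reference holds a gap are excluded, and the remaining columns are
#' indexed 1..L by reference position. Gap symbols of non-reference rows
#' count as a fifth symbol. For each column the variation is the proportion
#' of symbols different from the most frequent one; a column is conserved
#' when its most frequent symbol occupies at least `thr$conserved_col_min`
#' of the rows (boundary inclusive), and a conserved-adenine column is a
#' conserved column whose most frequent symbol is A. Ties for the most
#' frequent symbol break in the fixed order A < C < G < T < gap.
#'
#' @param msa aligned sequences of equal length: a named character vector, a
#'   `DNAStringSet`, or a character matrix (rows = sequences).
#' @param reference_id name of the reference sequence.
#' @param thr thresholds from [dgr_thresholds()].
#' @return A data.frame with one row per reference position: `position`,
#'   `n` (rows tallied), counts `A`, `C`, `G`, `T`, `gap`, `consensus`,
#'   `variation`, `conserved`, `conserved_A`.
#' @export
msa_column_stats <- function(msa, reference_id, thr = dgr_thresholds()) {
  m <- as_msa_matrix(msa)
  if (!(reference_id %in% rownames(m))) {
    stop("reference sequence '", reference_id, "' not present in the MSA")
  }
  ref <- m[reference_id, ]
  keep <- ref != "-"
  m <- m[, keep, drop = FALSE]
  n_seq <- nrow(m)
  symbols <- c("A", "C", "G", "T", "-")
  counts <- vapply(symbols, function(s) colSums(m == s),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)  # single position
  colnames(counts) <- symbols
  top_idx <- apply(counts, 1L, which.max)   # ties: first = A<C<G<T<gap order
  top_count <- counts[cbind(seq_len(nrow(counts)), top_idx)]
  data.frame(
    position = seq_len(nrow(counts)),
    n = n_seq,
    A = counts[, "A"], C = counts[, "C"],
    G = counts[, "G"], T = counts[, "T"], gap = counts[, "-"],
    consensus = symbols[top_idx],
    variation = 1 - top_count / n_seq,
    conserved = top_count / n_seq >= thr$conserved_col_min,
    conserved_A = top_count / n_seq >= thr$conserved_col_min &
      symbols[top_idx] == "A",
    row.names = NULL)
}

as_msa_matrix <- function(msa) {
  if (is.matrix(msa)) {
    m <- toupper(msa)
  } else {
    if (methods::is(msa, "DNAStringSet") || methods::is(msa, "XStringSet")) {
      msa <- setNames(as.character(msa), names(msa))
    }
    if (!is.character(msa) || length(msa) < 2L) {
      stop("msa must contain at least two aligned sequences")
    }
    lens <- nchar(msa)
    if (length(unique(lens)) != 1L) {
      stop("ragged alignment: sequences differ in length")
    }
    m <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
    rownames(m) <- names(msa)
  }
  if (is.null(rownames(m))) stop("msa sequences must be named")
  m[m == "."] <- "-"
  m
}

#' Windowed nucleotide-variation track
#'
#' Averages per-position variation (from [msa_column_stats()] or
#' [pileup_variation()]) over sliding windows; the conventional phage
#' windowing is 101 nt with a 20 nt step. A spike of windowed variation over
#' a DGR variable repeat, against a flat background, is the hallmark of
#' adenine-specific hypermutation at work in a set of cognate genomes.
#'
#' @param stats data.frame with `position` and `variation` columns, or a
#'   bare numeric vector of per-position variation.
#' @param spec a [window_spec()].
#' @return A data.frame with `start`, `end`, `variation` (mean over
#'   non-missing positions; `NA` when the window has none).
#' @export
variation_track <- function(stats, spec = phage_window_spec()) {
  v <- if (is.data.frame(stats)) {
    if (!nrow(stats)) stop("empty column statistics")
    stats$variation[order(stats$position)]
  } else as.numeric(stats)
  if (!length(v)) stop("empty column statistics")
  windows <- enumerate_windows(length(v), spec)
  out <- windows
  out$variation <- window_mean(v, windows)
  out
}

#' Windowed adenine-conservation track
#'
#' Per window, the percentage of conserved-adenine columns among all
#' conserved columns. DGR hypermutation consumes adenines at the variable
#' repeat, so the track dips at an active VR while variation spikes.
#' Windows containing no conserved column yield `NA` (the percentage is
#' undefined there, not 0 or 100).
#'
#' @param stats output of [msa_column_stats()].
#' @param spec a [window_spec()].
#' @return A data.frame with `start`, `end`, `n_conserved`, `adenine_pct`.
#' @export
adenine_conservation_track <- function(stats, spec = phage_window_spec()) {
  if (!nrow(stats)) stop("empty column statistics")
  stats <- stats[order(stats$position), ]
  windows <- enumerate_windows(nrow(stats), spec)
  out <- windows
  n_cons <- window_sum(stats$conserved, windows)
  n_a <- window_sum(stats$conserved_A, windows)
  pct <- 100 * n_a / n_cons
  pct[n_cons == 0] <- NA_real_
  out$n_conserved <- n_cons
  out$adenine_pct <- pct
  out
}
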