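#' Sliding-window specification
#'
#' A window specification is the triple (window, step, terminal extension),
#' all in nucleotides. Windows are laid along a sequence 5' to 3' starting at
#' position 1 with the given step; the last fully fitting window is extended
#' 3'-wards to absorb an uncovered tail of up to \code{extension} nt.
#'
#' Two conventions are used throughout: \code{bacterial_window_spec()}
#' (3001/500/1500) for bacterial contigs and \code{phage_window_spec()}
#' (101/20/50) for phage genomes and alignments.
#'
#' @param window window length in nt (positive).
#' @param step step between window starts in nt (positive, at most `window`).
#' @param extension maximum 3'-terminal tail, in nt, absorbed into the last
#'   window (nonnegative).
#' @return An object of class `window_spec`.
#' @examples
#' window_spec(101, 20, 50)
#' bacterial_window_spec()
#' @export
window_spec <- function(window, step, extension) {
  window <- as.integer(window); step <- as.integer(step)
  extension <- as.integer(extension)
  if (is.na(window) || window < 1L) stop("window must be a positive integer")
  if (is.na(step) || step < 1L) stop("step must be a positive integer")
  if (step > window) stop("step must not exceed window")
  if (is.na(extension) || extension < 0L) stop("extension must be nonnegative")
  structure(list(window = window, step = step, extension = extension),
            class = "window_spec")
}

#' @rdname window_spec
#' @export
bacterial_window_spec <- function() window_spec(3001L, 500L, 1500L)

#' @rdname window_spec
#' @export
phage_window_spec <- function() window_spec(101L, 20L, 50L)

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> window=%d step=%d extension=%d\n",
              x$window, x$step, x$extension))
  invisible(x)
}

#' Enumerate sliding windows over a sequence
#'
#' Window starts are 1, 1+step, 1+2*step, ... for as long as a full window
#' fits; the final window's end is raised to the sequence length when the
#' uncovered 3' tail is no longer than the spec's terminal extension. A
#' sequence shorter than one window yields the single window `[1, length]`.
#'
#' @param length sequence length in nt (positive).
#' @param spec a [window_spec()].
#' @return A data.frame with integer columns `start` and `end` (1-based,
#'   inclusive), ordered 5' to 3'.
#' @examples
#' enumerate_windows(4000, bacterial_window_spec())
#' enumerate_windows(101, phage_window_spec())
#' @export
enumerate_windows <- function(length, spec) {
  stopifnot(inherits(spec, "window_spec"))
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("sequence length must be positive")
  W <- spec$window; S <- spec$step; E <- spec$extension
  if (length < W) {
    return(data.frame(start = 1L, end = length))
  }
  starts <- seq.int(1L, length - W + 1L, by = S)
  ends <- starts + W - 1L
  tail_len <- length - ends[base::length(ends)]
  if (tail_len > 0L && tail_len <= E) {
    ends[base::length(ends)] <- length
  }
  data.frame(start = starts, end = ends)
}

## Mean of a per-position numeric vector within each window, via cumulative
## sums so enumerated windows of any width are O(1) each. NA positions are
## excluded from both numerator and count; all-NA windows give NA.
window_mean <- function(values, windows) {
  v <- as.numeric(values)
  ok <- !is.na(v)
  v[!ok] <- 0
  cs <- c(0, cumsum(v))
  cn <- c(0, cumsum(ok))
  num <- cs[windows$end + 1L] - cs[windows$start]
  den <- cn[windows$end + 1L] - cn[windows$start]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

## Sum variant of window_mean (NA treated as 0 contribution, count kept).
window_sum <- function(values, windows) {
  v <- as.numeric(values)
  v[is.na(v)] <- 0
  cs <- c(0, cumsum(v))
  cs[windows$end + 1L] - cs[windows$start]
}
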