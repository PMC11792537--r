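#' Default analysis thresholds
#'
#' Returns the full set of numeric thresholds used across the pipeline.
#' Each value can be overridden by passing it as a named argument; unknown
#' names are an error so typos do not silently fall back to defaults.
#'
#' The defaults encode the screening rules of the prophage/DGR workflow:
#' \describe{
#'   \item{contamination_breadth_max}{A virome sample whose reads cover more
#'     than this fraction (strictly) of the cumulative strain assembly length
#'     is treated as contaminated with bacterial DNA and excluded (0.25).}
#'   \item{metagenome_detect_breadth}{Read-breadth fraction at or above which a
#'     phage counts as detected in a bulk metagenome sample (0.75).}
#'   \item{isolate_detect_cov}{Fraction of the phage genome that must be
#'     covered by alignment hits to a single isolate contig to call the phage
#'     present in that isolate (0.95).}
#'   \item{cognate_cov}{Genome-coverage fraction defining a cognate database
#'     genome (0.95).}
#'   \item{cp_db_match_cov}{Fraction of a candidate-prophage region that must
#'     be covered by database hits to count as a database match (0.30).}
#'   \item{spacer_identity_min}{Minimum identity of a CRISPR spacer to its
#'     protospacer over the full spacer length (0.95).}
#'   \item{dgr_min_aln_len}{Minimum repeat-alignment length in columns (90).}
#'   \item{dgr_min_pid}{Minimum percent identity of a repeat alignment (50).}
#'   \item{dgr_min_mismatch}{Minimum number of substitution columns (5).}
#'   \item{dgr_min_a_fraction}{Minimum fraction of mismatch columns that hold
#'     adenine on one side, identifying the template repeat (0.75).}
#'   \item{conserved_col_min}{An MSA column is conserved when its most frequent
#'     symbol occupies at least this fraction of rows (0.90).}
#'   \item{rt_min_cov}{Minimum merged profile-envelope coverage, in amino acid
#'     residues, for a protein-profile annotation (100).}
#'   \item{pileup_min_depth}{Minimum per-position read depth for the pileup
#'     sample-inclusion rule (10).}
#'   \item{pileup_min_breadth}{Minimum fraction of genome positions at or above
#'     \code{pileup_min_depth} for a sample to be analyzed (0.95).}
#'   \item{ani_min}{Minimum average nucleotide identity, in percent, for
#'     species-level clustering (95).}
#'   \item{tcov_min}{Minimum alignment coverage of the shorter genome, in
#'     percent, for species-level clustering (85).}
#'   \item{seed_word}{Exact-match word length seeding the genome
#'     self-alignment (12).}
#' }
#'
#' @param ... named overrides of individual thresholds.
#' @return A named list of thresholds.
#' @examples
#' thr <- dgr_thresholds()
#' thr$dgr_min_aln_len
#' dgr_thresholds(dgr_min_pid = 60)$dgr_min_pid
#' @export
dgr_thresholds <- function(...) {
  thr <- list(
    contamination_breadth_max = 0.25,
    metagenome_detect_breadth = 0.75,
    isolate_detect_cov        = 0.95,
    cognate_cov               = 0.95,
    cp_db_match_cov           = 0.30,
    spacer_identity_min       = 0.95,
    dgr_min_aln_len           = 90L,
    dgr_min_pid               = 50,
    dgr_min_mismatch          = 5L,
    dgr_min_a_fraction        = 0.75,
    conserved_col_min         = 0.90,
    rt_min_cov                = 100L,
    pileup_min_depth          = 10L,
    pileup_min_breadth        = 0.95,
    ani_min                   = 95,
    tcov_min                  = 85,
    seed_word                 = 12L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots)))) {
      stop("threshold overrides must be named")
    }
    unknown <- setdiff(names(dots), names(thr))
    if (length(unknown)) {
      stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
    }
    thr[names(dots)] <- dots
  }
  frac <- c("contamination_breadth_max", "metagenome_detect_breadth",
            "isolate_detect_cov", "cognate_cov", "cp_db_match_cov",
            "spacer_identity_min", "dgr_min_a_fraction", "conserved_col_min",
            "pileup_min_breadth")
  for (f in frac) {
    v <- thr[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop("threshold '", f, "' must be a single fraction in [0, 1]")
    }
  }
  thr
}
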