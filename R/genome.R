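## Coercion helpers shared across modules. A "genome" argument may be a plain
## character scalar (optionally named), a Biostrings::DNAString, or a
## DNAStringSet of length one. Internally everything is an uppercase
## character string over {A,C,G,T,N}.

as_genome_seq <- function(genome, arg = "genome") {
  if (methods::is(genome, "DNAStringSet")) {
    if (length(genome) != 1L) {
      stop("'", arg, "' must contain exactly one sequence")
    }
    id <- names(genome)
    genome <- as.character(genome[[1L]])
    if (!is.null(id)) names(genome) <- id
  } else if (methods::is(genome, "DNAString") || methods::is(genome, "XString")) {
    genome <- as.character(genome)
  }
  if (!is.character(genome) || length(genome) != 1L || is.na(genome)) {
    stop("'", arg, "' must be a single nucleotide sequence")
  }
  if (nchar(genome) == 0L) stop("'", arg, "' is empty")
  out <- toupper(genome)
  names(out) <- if (is.null(names(genome))) arg else names(genome)
  out
}

## Validates alphabet and returns the position of the first offender.
check_nucleotides <- function(seq_chars) {
  bad <- which(!(seq_chars %in% c("A", "C", "G", "T", "N")))
  if (length(bad)) {
    stop(sprintf("invalid nucleotide '%s' at position %d",
                 seq_chars[bad[1L]], bad[1L]))
  }
  invisible(TRUE)
}

## 1-based inclusive interval constructor used in all reports.
interval <- function(contig_id, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("invalid interval: start must satisfy 1 <= start <= end")
  }
  list(contig_id = as.character(contig_id), start = start, end = end)
}

interval_len <- function(iv) iv$end - iv$start + 1L
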