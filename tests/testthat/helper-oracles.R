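## Independent brute-force oracles used to validate windowed statistics,
## interval arithmetic and the repeat detector. These deliberately loop over
## literal positions rather than reusing any package internals.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## literal per-window recount of nucleotide fractions
brute_content <- function(seq, windows) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  t(vapply(seq_len(nrow(windows)), function(w) {
    win <- chars[windows$start[w]:windows$end[w]]
    win <- win[win != "N"]
    if (!length(win)) return(rep(NA_real_, 4L))
    c(mean(win == "A"), mean(win == "C"), mean(win == "G"), mean(win == "T"))
  }, numeric(4L)))
}

brute_depth_breadth <- function(depth, windows) {
  t(vapply(seq_len(nrow(windows)), function(w) {
    d <- depth[windows$start[w]:windows$end[w]]
    c(mean(d), mean(d > 0))
  }, numeric(2L)))
}

brute_window_mean <- function(values, windows) {
  vapply(seq_len(nrow(windows)), function(w) {
    v <- values[windows$start[w]:windows$end[w]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1L))
}

## per-column MSA variation / conservation computed symbol by symbol
brute_msa_stats <- function(msa, reference_id, conserved_min = 0.9) {
  rows <- strsplit(toupper(msa), "", fixed = TRUE)
  ref <- rows[[which(names(msa) == reference_id)]]
  keep <- which(ref != "-")
  syms <- c("A", "C", "G", "T", "-")
  out <- data.frame(position = seq_along(keep), variation = NA_real_,
                    conserved = NA, conserved_A = NA)
  for (i in seq_along(keep)) {
    col <- vapply(rows, `[`, "", keep[i])
    counts <- vapply(syms, function(s) sum(col == s), numeric(1L))
    top <- max(counts)
    top_sym <- syms[which.max(counts)]
    out$variation[i] <- 1 - top / length(col)
    out$conserved[i] <- top / length(col) >= conserved_min
    out$conserved_A[i] <- out$conserved[i] && top_sym == "A"
  }
  out
}

brute_pileup_variation <- function(pileup) {
  vapply(seq_len(nrow(pileup)), function(i) {
    cts <- as.numeric(pileup[i, c("A", "C", "G", "T")])
    d <- sum(cts)
    if (d == 0) NA_real_ else 1 - max(cts) / d
  }, numeric(1L))
}

## per-residue marking oracle for interval-union coverage
brute_union_len <- function(starts, ends, len) {
  hit <- logical(len)
  for (i in seq_along(starts)) hit[starts[i]:ends[i]] <- TRUE
  sum(hit)
}

## exhaustive Hamming scan for spacer-protospacer matches
brute_spacer_scan <- function(spacer, genome, max_mm) {
  gl <- nchar(genome); sl <- nchar(spacer)
  g <- strsplit(genome, "", fixed = TRUE)[[1L]]
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") spacer else {
      chartr("ACGT", "TGCA",
             paste(rev(strsplit(spacer, "", fixed = TRUE)[[1L]]),
                   collapse = ""))
    }
    p <- strsplit(pat, "", fixed = TRUE)[[1L]]
    for (s in seq_len(gl - sl + 1L)) {
      mm <- sum(g[s:(s + sl - 1L)] != p)
      if (mm <= max_mm) {
        hits[[length(hits) + 1L]] <-
          data.frame(position = s, strand = strand, mismatches = mm)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(position = integer(), strand = character(),
                      mismatches = integer()))
  }
  do.call(rbind, hits)
}

## canonical key of an accepted repeat pair, for set comparison
pair_key <- function(p) {
  a <- p$alignment
  paste(a$interval_1$start, a$interval_1$end, a$interval_2$start,
        a$interval_2$end, a$orientation, a$aln_len, a$mismatches, sep = ":")
}

accepted_pairs <- function(alns, thr = dgr_thresholds()) {
  Filter(function(x) inherits(x, "repeat_pair"),
         lapply(alns, classify_dgr_pair, thr = thr))
}

## plant an inverted (opposite-strand) repeat copy by hand
plant_inverted_repeat <- function(seq, src_start, len, dest_start) {
  src <- substr(seq, src_start, src_start + len - 1L)
  inv <- chartr("ACGT", "TGCA",
                paste(rev(strsplit(src, "", fixed = TRUE)[[1L]]),
                      collapse = ""))
  paste0(substr(seq, 1L, dest_start - 1L), inv,
         substr(seq, dest_start + len, nchar(seq)))
}

## construct a repeat_alignment object directly from two aligned strings
make_alignment <- function(aln1, aln2, orientation = "same",
                           s1 = 1000L, s2 = 5000L) {
  len1 <- nchar(gsub("-", "", aln1))
  len2 <- nchar(gsub("-", "", aln2))
  dgrscan:::new_repeat_alignment("test_contig", s1, s1 + len1 - 1L,
                                 s2, s2 + len2 - 1L, orientation,
                                 aln1, aln2, score = 100L)
}

## aligned string pair with given identities / mismatch composition;
## mism_bases is a two-row matrix of characters (side1, side2) per mismatch
make_pair_strings <- function(n_ident, mism_bases, ident_base = "G") {
  stopifnot(is.matrix(mism_bases), nrow(mism_bases) == 2L)
  a1 <- c(rep(ident_base, n_ident), mism_bases[1L, ])
  a2 <- c(rep(ident_base, n_ident), mism_bases[2L, ])
  list(aln1 = paste(a1, collapse = ""), aln2 = paste(a2, collapse = ""))
}
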