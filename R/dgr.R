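#' Classify a repeat alignment as a DGR template/variable repeat pair
#'
#' A repeat pair qualifies as a DGR repeat pair when the alignment is at
#' least 90 columns long, at least 50 percent identical, carries at least 5
#' mismatches, and at least 75 percent of the mismatch columns hold adenine
#' on one of the two sides, read on either strand (a minus-strand template
#' repeat shows its adenine bias as thymine in a plus-strand alignment).
#' The adenine-biased side is the template repeat (TR): DGR reverse
#' transcription copies the TR through an error-prone process that
#' substitutes specifically at TR adenines, so the variable repeat (VR)
#' accumulates differences exactly where the TR holds A. Gap columns are
#' neither mismatches nor part of the adenine-fraction denominator.
#'
#' @param aln a `repeat_alignment` from [find_repeat_alignments()].
#' @param thr thresholds from [dgr_thresholds()].
#' @return A list of class `repeat_pair` when accepted, with the alignment,
#'   `a_mismatch_fraction_1`/`_2`, `t_mismatch_fraction_1`/`_2`, `tr`/`vr`
#'   (1 or 2, the alignment side), `tr_strand` (`"+"` when the bias is read
#'   as adenine on the aligned strand, `"-"` when as thymine),
#'   `tr_interval`/`vr_interval`, and per-side genomic mismatch positions
#'   (`mismatch_pos_1`, `mismatch_pos_2`). When rejected, a list of class
#'   `repeat_rejection` with a `reason` in
#'   `c("aln_len", "pid", "mismatches", "a_fraction")`.
#' @export
classify_dgr_pair <- function(aln, thr = dgr_thresholds()) {
  stopifnot(inherits(aln, "repeat_alignment"))
  reject <- function(reason) {
    structure(list(alignment = aln, reason = reason),
              class = "repeat_rejection")
  }
  if (aln$aln_len < thr$dgr_min_aln_len) return(reject("aln_len"))
  if (aln$pid < thr$dgr_min_pid) return(reject("pid"))
  if (aln$mismatches < thr$dgr_min_mismatch) return(reject("mismatches"))
  c1 <- strsplit(aln$aln1, "", fixed = TRUE)[[1L]]
  c2 <- strsplit(aln$aln2, "", fixed = TRUE)[[1L]]
  mm <- aln$mismatch_cols
  a1 <- sum(c1[mm] == "A") / length(mm)
  a2 <- sum(c2[mm] == "A") / length(mm)
  ## a template repeat read on the opposite strand shows its adenine bias
  ## as thymine in this alignment; checking both readings keeps the
  ## classification invariant under reverse complement of the genome
  t1 <- sum(c1[mm] == "T") / length(mm)
  t2 <- sum(c2[mm] == "T") / length(mm)
  fracs <- c(a1, a2, t1, t2)
  if (max(fracs) < thr$dgr_min_a_fraction) return(reject("a_fraction"))
  best <- which.max(fracs)
  tr_side <- if (best %in% c(1L, 3L)) 1L else 2L
  tr_strand <- if (best <= 2L) "+" else "-"

  pos1 <- aln$interval_1$start - 1L + cumsum(c1 != "-")
  if (aln$orientation == "opposite") {
    ## aln2 runs along the minus strand: columns advance 3'->5' in genome
    pos2 <- aln$interval_2$end + 1L - cumsum(c2 != "-")
  } else {
    pos2 <- aln$interval_2$start - 1L + cumsum(c2 != "-")
  }
  structure(list(
    alignment = aln,
    a_mismatch_fraction_1 = a1,
    a_mismatch_fraction_2 = a2,
    t_mismatch_fraction_1 = t1,
    t_mismatch_fraction_2 = t2,
    tr = tr_side, vr = 3L - tr_side, tr_strand = tr_strand,
    tr_interval = if (tr_side == 1L) aln$interval_1 else aln$interval_2,
    vr_interval = if (tr_side == 1L) aln$interval_2 else aln$interval_1,
    mismatch_pos_1 = pos1[aln$mismatch_cols],
    mismatch_pos_2 = pos2[aln$mismatch_cols]),
    class = "repeat_pair")
}

#' @export
print.repeat_pair <- function(x, ...) {
  cat(sprintf("<repeat_pair> TR %d-%d / VR %d-%d, %d mismatches, A-frac %.2f\n",
              x$tr_interval$start, x$tr_interval$end,
              x$vr_interval$start, x$vr_interval$end,
              x$alignment$mismatches,
              max(x$a_mismatch_fraction_1, x$a_mismatch_fraction_2)))
  invisible(x)
}

#' Merge profile-hit envelopes per protein and profile
#'
#' Profile searches report one row per domain hit; hits of the same profile
#' on the same protein are unioned over their envelope coordinates so that
#' coverage counts each residue once.
#'
#' @param hits data.frame with columns `protein_id`, `profile_id`,
#'   `env_start`, `env_end` (1-based amino acid, inclusive) and optionally
#'   `evalue`.
#' @return A data.frame with one row per (protein, profile): merged
#'   `coverage` in residues and the smallest `evalue` (NA when absent).
#' @export
merge_domain_envelopes <- function(hits) {
  hits <- as.data.frame(hits)
  need <- c("protein_id", "profile_id", "env_start", "env_end")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hits lack column(s): ", paste(miss, collapse = ", "))
  if (any(hits$env_start > hits$env_end)) {
    stop("domain hit with env_start > env_end")
  }
  if (!nrow(hits)) {
    return(data.frame(protein_id = character(), profile_id = character(),
                      coverage = integer(), evalue = numeric()))
  }
  key <- paste(hits$protein_id, hits$profile_id, sep = "\r")
  parts <- split(seq_len(nrow(hits)), key)
  out <- lapply(parts, function(idx) {
    ir <- IRanges::reduce(IRanges::IRanges(hits$env_start[idx],
                                           hits$env_end[idx]))
    data.frame(protein_id = hits$protein_id[idx[1L]],
               profile_id = hits$profile_id[idx[1L]],
               coverage = sum(IRanges::width(ir)),
               evalue = if ("evalue" %in% names(hits)) {
                 min(hits$evalue[idx])
               } else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$protein_id, out$profile_id), , drop = FALSE]
}

#' Annotate proteins by their best-covered profile
#'
#' Keeps only protein-profile pairs whose merged envelope coverage reaches
#' `thr$rt_min_cov` residues; among survivors the profile with maximal
#' coverage annotates the protein, ties broken by smaller e-value and then
#' lexicographic profile id. Proteins whose winning profile is `rt_profile`
#' are flagged as reverse-transcriptase (RT) genes, the enzymatic core of a
#' DGR.
#'
#' @param hits data.frame of domain hits as for [merge_domain_envelopes()].
#' @param thr thresholds from [dgr_thresholds()].
#' @param rt_profile profile id marking reverse transcriptases
#'   (default `"RVT_1"`).
#' @return A data.frame with one row per annotated protein: `protein_id`,
#'   `profile_id`, `coverage`, `evalue`, `is_rt`. Proteins with no profile
#'   at sufficient coverage are absent.
#' @export
annotate_proteins <- function(hits, thr = dgr_thresholds(),
                              rt_profile = "RVT_1") {
  merged <- merge_domain_envelopes(hits)
  merged <- merged[merged$coverage >= thr$rt_min_cov, , drop = FALSE]
  if (!nrow(merged)) {
    return(data.frame(protein_id = character(), profile_id = character(),
                      coverage = integer(), evalue = numeric(),
                      is_rt = logical()))
  }
  ev <- ifelse(is.na(merged$evalue), Inf, merged$evalue)
  o <- order(merged$protein_id, -merged$coverage, ev, merged$profile_id)
  merged <- merged[o, , drop = FALSE]
  merged <- merged[!duplicated(merged$protein_id), , drop = FALSE]
  merged$is_rt <- merged$profile_id == rt_profile
  rownames(merged) <- NULL
  merged
}

overlap_len <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}

reciprocal_overlap <- function(iv1, iv2) {
  ov <- overlap_len(iv1$start, iv1$end, iv2$start, iv2$end)
  min(ov / interval_len(iv1), ov / interval_len(iv2))
}

## aa span of a genomic interval within an ORF, strand- and frame-aware
vr_protein_span <- function(vr, orf) {
  s <- max(vr$start, orf$start); e <- min(vr$end, orf$end)
  if (s > e) return(NULL)
  if (orf$strand == "+") {
    aa <- c(floor((s - orf$start) / 3) + 1L, floor((e - orf$start) / 3) + 1L)
  } else {
    aa <- c(floor((orf$end - e) / 3) + 1L, floor((orf$end - s) / 3) + 1L)
  }
  list(aa_start = aa[1L], aa_end = aa[2L],
       partial = vr$start < orf$start || vr$end > orf$end)
}

#' Assemble DGR loci from classified repeat pairs
#'
#' Groups repeat pairs whose template repeats reciprocally overlap by at
#' least 50 percent into single loci (a DGR with one TR may serve several
#' VRs), attaches the nearest reverse-transcriptase ORF with its distance,
#' and maps every VR into protein coordinates of the ORF it lies in (the
#' DGR target gene). VRs outside any ORF are flagged intergenic; VRs
#' spanning an ORF boundary are mapped to the overlapped codons and flagged
#' partial.
#'
#' @param pairs list of `repeat_pair` objects from [classify_dgr_pair()].
#' @param rt_orfs data.frame of RT gene ORFs (`start`, `end`, `strand`),
#'   or NULL/empty when no RT gene is known.
#' @param orfs data.frame of all ORFs on the genome (`start`, `end`,
#'   `strand`).
#' @param genome_len genome length in nt; required for `circular = TRUE`.
#' @param circular treat the genome as circular when measuring the TR-RT
#'   distance.
#' @param rt_flag_distance loci whose nearest RT lies farther than this are
#'   flagged for review (default 10000 nt); no locus is dropped for
#'   distance.
#' @return A list of `dgr_locus` objects: `tr` (union TR interval), `vrs`
#'   (list of VR intervals), `pairs`, `rt_orf` (row or NULL), `rt_distance`,
#'   `rt_far_flag`, `targets` (one entry per VR: `orf`, `aa_start`,
#'   `aa_end`, `partial`, or `intergenic = TRUE`).
#' @export
assemble_loci <- function(pairs, rt_orfs = NULL, orfs = NULL,
                          genome_len = NULL, circular = FALSE,
                          rt_flag_distance = 10000L) {
  pairs <- Filter(function(p) inherits(p, "repeat_pair"), pairs)
  if (!length(pairs)) return(list())
  if (!is.null(orfs)) orfs <- validate_orfs(orfs)
  if (!is.null(rt_orfs)) rt_orfs <- validate_orfs(rt_orfs)

  n <- length(pairs)
  group <- integer(n)
  n_grp <- 0L
  reps <- list()  # running union TR per group
  for (i in seq_len(n)) {
    tr <- pairs[[i]]$tr_interval
    hit <- 0L
    for (g in seq_len(n_grp)) {
      if (reciprocal_overlap(tr, reps[[g]]) >= 0.5) { hit <- g; break }
    }
    if (hit == 0L) {
      n_grp <- n_grp + 1L
      hit <- n_grp
      reps[[hit]] <- tr
    } else {
      reps[[hit]] <- interval(tr$contig_id,
                              min(tr$start, reps[[hit]]$start),
                              max(tr$end, reps[[hit]]$end))
    }
    group[i] <- hit
  }

  gap_distance <- function(iv, s, e) {
    if (overlap_len(iv$start, iv$end, s, e) > 0L) return(0L)
    d <- if (e < iv$start) iv$start - e else s - iv$end
    if (circular) {
      if (is.null(genome_len)) stop("circular distance requires genome_len")
      wrap <- genome_len - max(iv$end, e) + min(iv$start, s)
      d <- min(d, wrap)
    }
    d
  }

  loci <- vector("list", n_grp)
  for (g in seq_len(n_grp)) {
    members <- pairs[group == g]
    tr <- reps[[g]]
    vrs <- lapply(members, function(p) p$vr_interval)
    rt_orf <- NULL; rt_distance <- NA_integer_
    if (!is.null(rt_orfs) && nrow(rt_orfs)) {
      dists <- mapply(function(s, e) gap_distance(tr, s, e),
                      rt_orfs$start, rt_orfs$end)
      best <- which.min(dists)
      rt_orf <- rt_orfs[best, , drop = FALSE]
      rt_distance <- as.integer(dists[best])
    } else {
      warning("DGR locus assembled without an RT ORF", call. = FALSE)
    }
    targets <- lapply(vrs, function(vr) {
      if (is.null(orfs) || !nrow(orfs)) {
        return(list(intergenic = TRUE))
      }
      ov <- mapply(function(s, e) overlap_len(vr$start, vr$end, s, e),
                   orfs$start, orfs$end)
      if (all(ov == 0L)) return(list(intergenic = TRUE))
      orf <- orfs[which.max(ov), , drop = FALSE]
      span <- vr_protein_span(vr, orf)
      c(list(intergenic = FALSE, orf = orf), span)
    })
    loci[[g]] <- structure(list(
      tr = tr, vrs = vrs, pairs = members,
      rt_orf = rt_orf, rt_distance = rt_distance,
      rt_far_flag = !is.na(rt_distance) && rt_distance > rt_flag_distance,
      targets = targets), class = "dgr_locus")
  }
  loci
}

#' @export
print.dgr_locus <- function(x, ...) {
  cat(sprintf("<dgr_locus> TR %d-%d, %d VR(s), RT %s\n",
              x$tr$start, x$tr$end, length(x$vrs),
              if (is.null(x$rt_orf)) "missing"
              else sprintf("at %d nt", x$rt_distance)))
  invisible(x)
}
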