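test_that("self-alignment finds planted repeat pairs with exact bookkeeping", {
  set.seed(7)
  base <- rand_seq(4000)
  copy <- substr(base, 1001, 1150)
  ## guard bases mismatching the first occurrence's flanks pin the local
  ## alignment exactly to the planted copy
  gl <- setdiff(c("A", "C", "G", "T"), substr(base, 1000, 1000))[1L]
  gr <- setdiff(c("A", "C", "G", "T"), substr(base, 1151, 1151))[1L]
  g1 <- setNames(paste0(base, gl, copy, gr, rand_seq(500)), "g")
  a1 <- find_repeat_alignments(g1)
  expect_length(a1, 1L)
  expect_equal(a1[[1]]$pid, 100)
  expect_equal(a1[[1]]$mismatches, 0L)
  expect_equal(a1[[1]]$interval_1[c("start", "end")],
               list(start = 1001L, end = 1150L))
  expect_equal(a1[[1]]$interval_2[c("start", "end")],
               list(start = 4002L, end = 4151L))

  ## planted pair differing at 8 interior positions
  chars <- strsplit(copy, "", fixed = TRUE)[[1L]]
  at <- seq(10, 140, length.out = 8)
  for (p in at) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1L]
  g2 <- setNames(paste0(base, gl, paste(chars, collapse = ""), gr,
                        rand_seq(500)), "g")
  a2 <- find_repeat_alignments(g2)
  expect_length(a2, 1L)
  expect_equal(a2[[1]]$aln_len, 150L)
  expect_equal(a2[[1]]$mismatches, 8L)

  expect_error(find_repeat_alignments(setNames("ACGT", "tiny")), "shorter")
})

test_that("seeded search agrees with the exhaustive enumeration", {
  set.seed(21)
  for (rep in 1:6) {
    g <- setNames(rand_seq(2500), "g")
    if (rep > 2) {
      d <- plant_dgr(rep, g, tr_len = 110 + 10 * (rep %% 3),
                     n_vr = 1 + rep %% 2, adenine_sub_count = 6 + rep)
      g <- d$genome
    }
    seeded <- accepted_pairs(find_repeat_alignments(g))
    oracle <- accepted_pairs(exhaustive_repeat_alignments(g))
    expect_setequal(vapply(seeded, pair_key, ""),
                    vapply(oracle, pair_key, ""))
  }
})

test_that("opposite-strand repeats are reported with opposite orientation", {
  set.seed(33)
  seq <- rand_seq(3000)
  seq <- plant_inverted_repeat(seq, 501, 130, 2201)
  a <- find_repeat_alignments(setNames(seq, "g"))
  expect_length(a, 1L)
  expect_equal(a[[1]]$orientation, "opposite")
  expect_equal(a[[1]]$interval_1$start, 501L)
  expect_equal(a[[1]]$interval_2[c("start", "end")],
               list(start = 2201L, end = 2330L))
})

test_that("DGR pair classification applies all gates with stated boundaries", {
  thr <- dgr_thresholds()
  ## 89 columns, adenine-biased mismatches: rejected on length alone
  p89 <- make_pair_strings(79, matrix(c(rep("A", 10), rep("C", 10)),
                                      nrow = 2, byrow = TRUE))
  r <- classify_dgr_pair(make_alignment(p89$aln1, p89$aln2), thr)
  expect_s3_class(r, "repeat_rejection")
  expect_equal(r$reason, "aln_len")

  ## identical repeats: no mismatches
  ident <- strrep("G", 120)
  r0 <- classify_dgr_pair(make_alignment(ident, ident), thr)
  expect_equal(r0$reason, "mismatches")

  ## 120 columns, 8 mismatches, 7 adenine on side 1: accepted, TR = side 1
  p <- make_pair_strings(112, matrix(c(rep("A", 7), "C",
                                       rep("C", 7), "G"),
                                     nrow = 2, byrow = TRUE))
  acc <- classify_dgr_pair(make_alignment(p$aln1, p$aln2), thr)
  expect_s3_class(acc, "repeat_pair")
  expect_equal(acc$a_mismatch_fraction_1, 7 / 8)
  expect_equal(acc$tr, 1L)
  expect_equal(acc$tr_strand, "+")

  ## swapping the sides swaps TR/VR labels and nothing else
  swap <- classify_dgr_pair(make_alignment(p$aln2, p$aln1), thr)
  expect_equal(swap$tr, 2L)
  expect_equal(swap$a_mismatch_fraction_2, 7 / 8)
  expect_equal(swap$alignment$mismatches, acc$alignment$mismatches)

  ## gap columns are not mismatches and not in the A-fraction denominator
  g1 <- paste0(strrep("G", 100), "A-", strrep("A", 6))
  g2 <- paste0(strrep("G", 100), "-C", strrep("C", 6))
  withgap <- classify_dgr_pair(make_alignment(g1, g2), thr)
  expect_s3_class(withgap, "repeat_pair")
  expect_equal(withgap$alignment$mismatches, 6L)
  expect_equal(withgap$a_mismatch_fraction_1, 1)
})

test_that("minus-strand template repeats are classified via the T reading", {
  ## T-biased side 1: adenine bias on the complementary strand
  p <- make_pair_strings(112, matrix(c(rep("T", 8), rep("G", 8)),
                                     nrow = 2, byrow = TRUE))
  r <- classify_dgr_pair(make_alignment(p$aln1, p$aln2))
  expect_s3_class(r, "repeat_pair")
  expect_equal(r$tr, 1L)
  expect_equal(r$tr_strand, "-")
})

test_that("reverse-complementing the genome yields mirrored loci", {
  set.seed(55)
  g <- setNames(rand_seq(4000), "g")
  d <- plant_dgr(56, g, tr_len = 120, n_vr = 2, adenine_sub_count = 8)
  L <- nchar(d$genome)
  fwd <- accepted_pairs(find_repeat_alignments(d$genome))
  rcg <- setNames(chartr("ACGT", "TGCA",
                         paste(rev(strsplit(d$genome, "")[[1L]]),
                               collapse = "")), "g")
  rev_ <- accepted_pairs(find_repeat_alignments(rcg))
  expect_length(rev_, length(fwd))
  mirror <- function(iv) c(L - iv$end + 1L, L - iv$start + 1L)
  fwd_trs <- lapply(fwd, function(p) c(p$tr_interval$start, p$tr_interval$end))
  rev_trs <- lapply(rev_, function(p) mirror(p$tr_interval))
  expect_setequal(vapply(fwd_trs, paste, "", collapse = "-"),
                  vapply(rev_trs, paste, "", collapse = "-"))
})

test_that("envelope merging equals per-residue marking", {
  h <- data.frame(protein_id = "p", profile_id = "X",
                  env_start = c(1L, 50L), env_end = c(60L, 120L))
  expect_equal(merge_domain_envelopes(h)$coverage, 120L)
  h2 <- data.frame(protein_id = "p", profile_id = "X",
                   env_start = c(1L, 100L), env_end = c(40L, 140L))
  expect_equal(merge_domain_envelopes(h2)$coverage, 81L)
  expect_error(merge_domain_envelopes(
    data.frame(protein_id = "p", profile_id = "X",
               env_start = 10L, env_end = 5L)), "env_start")

  set.seed(60)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    s <- sample.int(300, n, replace = TRUE)
    e <- pmin(300L, s + sample.int(80, n, replace = TRUE))
    mh <- data.frame(protein_id = "p", profile_id = "X",
                     env_start = s, env_end = e)
    expect_equal(merge_domain_envelopes(mh)$coverage,
                 brute_union_len(s, e, 300L))
  }
})

test_that("protein annotation picks maximal coverage with stated tie-breaks", {
  thr <- dgr_thresholds()
  ## coverage 99 residues: below the floor, no annotation
  a99 <- annotate_proteins(data.frame(protein_id = "p", profile_id = "X",
                                      env_start = 1L, env_end = 99L,
                                      evalue = 1e-50), thr)
  expect_equal(nrow(a99), 0L)

  two <- data.frame(protein_id = "p", profile_id = c("X", "Y"),
                    env_start = 1L, env_end = c(150L, 120L),
                    evalue = c(1e-10, 1e-40))
  expect_equal(annotate_proteins(two, thr)$profile_id, "X")

  tie <- data.frame(protein_id = "p", profile_id = c("X", "Y"),
                    env_start = 1L, env_end = 120L,
                    evalue = c(1e-30, 1e-10))
  expect_equal(annotate_proteins(tie, thr)$profile_id, "X")

  rt <- data.frame(protein_id = c("p", "q"), profile_id = c("RVT_1", "Phage_cap"),
                   env_start = 1L, env_end = 200L, evalue = 1e-30)
  ann <- annotate_proteins(rt, thr)
  expect_equal(ann$is_rt, c(TRUE, FALSE))

  ## never annotates below 100 aa merged coverage
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(1:6, 1)
    s <- sample.int(400, n, replace = TRUE)
    hh <- data.frame(protein_id = "p",
                     profile_id = sample(c("X", "Y"), n, replace = TRUE),
                     env_start = s, env_end = pmin(400L, s + 60L),
                     evalue = 1e-5)
    ann <- annotate_proteins(hh, thr)
    if (nrow(ann)) expect_true(all(ann$coverage >= 100L))
  }
})

test_that("locus assembly groups shared TRs and maps VRs to codons", {
  set.seed(70)
  g <- setNames(rand_seq(6000), "g")
  d <- plant_dgr(71, g, tr_len = 120, n_vr = 2, adenine_sub_count = 8)
  pairs <- accepted_pairs(find_repeat_alignments(d$genome))
  expect_length(pairs, 2L)
  loci <- assemble_loci(pairs, rt_orfs = d$truth$rt_orf)
  expect_length(loci, 1L)
  expect_length(loci[[1]]$vrs, 2L)
  expect_false(loci[[1]]$rt_far_flag)

  ## VR at nt 301-420 inside a + strand ORF starting at 1 -> aa 101-140
  p <- pairs[[1]]
  p$vr_interval <- dgrscan:::interval("g", 301L, 420L)
  orfs <- data.frame(start = 1L, end = 900L, strand = "+")
  l <- assemble_loci(list(p), rt_orfs = d$truth$rt_orf, orfs = orfs)
  tgt <- l[[1]]$targets[[1]]
  expect_equal(c(tgt$aa_start, tgt$aa_end), c(101L, 140L))
  expect_false(tgt$partial)

  ## minus strand: aa counted from the ORF 3' end
  orfs_m <- data.frame(start = 1L, end = 900L, strand = "-")
  lm <- assemble_loci(list(p), rt_orfs = d$truth$rt_orf, orfs = orfs_m)
  tm <- lm[[1]]$targets[[1]]
  expect_equal(c(tm$aa_start, tm$aa_end),
               c(floor((900 - 420) / 3) + 1L, floor((900 - 301) / 3) + 1L))

  ## VR outside every ORF is intergenic; missing RT warns
  far <- data.frame(start = 5000L, end = 5300L, strand = "+")
  li <- assemble_loci(list(p), rt_orfs = d$truth$rt_orf, orfs = far)
  expect_true(li[[1]]$targets[[1]]$intergenic)
  expect_warning(assemble_loci(list(p), rt_orfs = NULL), "without an RT")
})
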