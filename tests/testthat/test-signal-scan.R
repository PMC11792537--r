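test_that("ORF organization statistics match hand-computed values", {
  spec <- window_spec(1000, 1000, 500)
  orfs <- data.frame(start = c(1L, 401L), end = c(300L, 700L),
                     strand = c("+", "+"))
  t1 <- orf_organization_track(orfs, 1000L, spec)
  expect_equal(t1$median_orf_len, 300)
  expect_equal(t1$median_gap, 100)
  expect_equal(t1$strand_switches, 0)
  expect_equal(t1$coding_density, 0.6)

  orfs4 <- data.frame(start = c(1, 101, 201, 301), end = c(90, 190, 290, 390),
                      strand = c("+", "-", "+", "-"))
  t2 <- orf_organization_track(orfs4, 400L, window_spec(400, 400, 0))
  expect_equal(t2$strand_switches, 3)

  ## <2 ORFs in a window: explicit missing, never silent zeros
  t3 <- orf_organization_track(orfs[1, ], 1000L, spec)
  expect_true(is.na(t3$median_orf_len))
  expect_error(orf_organization_track(data.frame(start = 1, end = 2000,
                                                 strand = "+"), 1000L, spec),
               "bounds")
})

test_that("prophage regions show shorter genes than host regions", {
  hits <- 0L
  n_runs <- 25L
  for (s in seq_len(n_runs)) {
    sim <- simulate_host_with_prophage(s, host_len = 60000L,
                                       prophage_len = 20000L)
    tr <- orf_organization_track(sim$orfs, 60000L)
    pro <- sim$truth$prophage
    in_pro <- tr$start >= pro$start & tr$end <= pro$end
    in_host <- tr$end < pro$start | tr$start > pro$end
    med_pro <- median(tr$median_orf_len[in_pro], na.rm = TRUE)
    med_host <- median(tr$median_orf_len[in_host], na.rm = TRUE)
    hits <- hits + (med_pro < med_host)
  }
  expect_gte(hits / n_runs, 0.95)
})

test_that("contamination filter uses cumulative breadth with a strict boundary", {
  ## breadth 0.30 -> excluded; exactly 0.25 -> included; 0 -> included
  d30 <- list(c1 = c(rep(1L, 30), rep(0L, 70)))
  expect_true(contamination_filter(d30)$exclude)
  d25 <- list(c1 = c(rep(1L, 25), rep(0L, 75)))
  f25 <- contamination_filter(d25)
  expect_equal(f25$breadth, 0.25)
  expect_false(f25$exclude)
  expect_false(contamination_filter(list(c1 = rep(0L, 50)))$exclude)

  ## cumulative over contigs, invariant under contig reordering
  dd <- list(a = c(rep(2L, 40), rep(0L, 60)), b = rep(0L, 100))
  f <- contamination_filter(dd)
  expect_equal(f$breadth, 0.2)
  expect_equal(contamination_filter(rev(dd))$breadth, f$breadth)
  expect_error(contamination_filter(dd, contig_lengths = c(a = 100, z = 50)),
               "missing depth")
})

test_that("coverage ratio recovers planted induction levels", {
  d <- c(rep(1, 100), rep(200, 50), rep(1, 100))
  expect_equal(coverage_ratio(d, list(start = 101, end = 150))$ratio, 200)
  expect_equal(coverage_ratio(rep(7, 300), list(start = 10, end = 40))$ratio, 1)
  r0 <- coverage_ratio(c(rep(0, 50), rep(9, 10), rep(0, 40)),
                       list(start = 51, end = 60))
  expect_true(r0$infinite)
  expect_identical(r0$ratio, Inf)
  expect_error(coverage_ratio(rep(1, 10), list(start = 1, end = 10)), "whole")
  expect_error(coverage_ratio(rep(1, 10), list(start = 5, end = 11)), "within")
})

test_that("candidate-region caller finds planted prophages, not flat tracks", {
  flat <- data.frame(start = seq(1, 99001, 500))
  flat$end <- flat$start + 3000
  flat$sig1 <- 1; flat$sig2 <- 5
  expect_equal(nrow(call_candidate_regions(flat)), 0L)

  found <- 0L; n_runs <- 20L
  for (s in seq_len(n_runs)) {
    sim <- simulate_host_with_prophage(1000L + s, host_len = 120000L,
                                       prophage_len = 40000L)
    dep <- simulate_depth_profile(2000L + s, 120000L,
                                  prophage = sim$truth$prophage,
                                  base_depth = 5, ratio = 40)
    og <- orf_organization_track(sim$orfs, 120000L)
    db <- depth_breadth_tracks(dep$depth)
    nt <- nucleotide_content_track(sim$genome)
    tracks <- data.frame(start = og$start, end = og$end,
                         gc = nt$G + nt$C,
                         median_orf_len = og$median_orf_len,
                         mean_depth = db$mean_depth, breadth = db$breadth)
    regions <- call_candidate_regions(
      tracks, directions = c(gc = -1, median_orf_len = -1,
                             mean_depth = 1, breadth = 1))
    pro <- sim$truth$prophage
    if (nrow(regions) == 1L) {
      ov <- max(0, min(regions$end[1], pro$end) -
                  max(regions$start[1], pro$start) + 1)
      if (ov / (pro$end - pro$start + 1) >= 0.8) found <- found + 1L
    }
  }
  expect_gte(found / n_runs, 0.9)
})

test_that("shuffled tracks rarely produce candidate regions", {
  sim <- simulate_host_with_prophage(77L, host_len = 120000L,
                                     prophage_len = 40000L)
  dep <- simulate_depth_profile(78L, 120000L, prophage = sim$truth$prophage,
                                base_depth = 5, ratio = 40)
  og <- orf_organization_track(sim$orfs, 120000L)
  db <- depth_breadth_tracks(dep$depth)
  tracks <- data.frame(start = og$start, end = og$end,
                       median_orf_len = og$median_orf_len,
                       mean_depth = db$mean_depth, breadth = db$breadth)
  set.seed(79)
  fp <- 0L
  for (i in 1:100) {
    shuf <- tracks
    for (cn in c("median_orf_len", "mean_depth", "breadth")) {
      shuf[[cn]] <- sample(shuf[[cn]])
    }
    if (nrow(call_candidate_regions(
      shuf, directions = c(median_orf_len = -1, mean_depth = 1,
                           breadth = 1))) > 0) fp <- fp + 1L
  }
  expect_lte(fp / 100, 0.05)
})

test_that("terminus caller reports the two modal junction clusters", {
  j <- data.frame(position = c(100L, 101L, 5000L), count = c(50L, 3L, 40L))
  t1 <- call_transposable_termini(j)
  expect_equal(c(t1$left, t1$right), c(100L, 5000L))
  expect_equal(t1$support, c(50, 40))

  ## degenerate single cluster
  t2 <- call_transposable_termini(data.frame(position = 250L, count = 10L))
  expect_equal(t2$left, 250L)
  expect_true(is.na(t2$right))

  ## permutation invariance of the input rows
  set.seed(11)
  jr <- data.frame(position = sample(c(rep(900L, 30), rep(44000L, 25),
                                       sample.int(100000L, 45))))
  t3 <- call_transposable_termini(jr)
  t4 <- call_transposable_termini(jr[sample(nrow(jr)), , drop = FALSE])
  expect_identical(t3, t4)

  expect_error(call_transposable_termini(data.frame(position = integer())),
               "no junction")
})
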