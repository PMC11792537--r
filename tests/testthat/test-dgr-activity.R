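test_that("MSA column statistics follow the stated definitions", {
  msa <- c(ref = "AAAA", s1 = "AAAA", s2 = "AAAA", s3 = "AAAA")
  st <- msa_column_stats(msa, "ref")
  expect_equal(st$variation, rep(0, 4))
  expect_true(all(st$conserved))
  expect_true(all(st$conserved_A))

  ## 9 A + 1 C: variation 0.1, conserved at the inclusive 0.9 boundary
  msa10 <- setNames(c("A", rep("A", 8), "C"),
                    c("ref", paste0("s", 1:9)))
  st10 <- msa_column_stats(msa10, "ref")
  expect_equal(st10$variation, 0.1)
  expect_true(st10$conserved)
  expect_true(st10$conserved_A)

  ## 5 A + 5 C tie: variation 0.5, not conserved, consensus A by tie order
  msa55 <- setNames(c(rep("A", 5), rep("C", 5)), paste0("s", 1:10))
  st55 <- msa_column_stats(msa55, "s1")
  expect_equal(st55$variation, 0.5)
  expect_false(st55$conserved)
  expect_equal(st55$consensus, "A")

  ## reference-gap columns are dropped; non-reference gaps are a 5th symbol
  msag <- c(ref = "A-CG", s1 = "AAC-", s2 = "AAC-")
  stg <- msa_column_stats(msag, "ref")
  expect_equal(nrow(stg), 3L)
  expect_equal(stg$gap, c(0, 0, 2))
  expect_equal(stg$variation, c(0, 0, 1 / 3))

  expect_error(msa_column_stats(c(a = "ACG", b = "AC"), "a"), "ragged")
  expect_error(msa_column_stats(c(a = "ACG", b = "ACG"), "zz"), "not present")
})

test_that("row order and all-gap columns never change reference-indexed output", {
  set.seed(90)
  g <- setNames(rand_seq(800), "ref")
  d <- plant_dgr(91, g, tr_len = 100, n_vr = 1, adenine_sub_count = 6)
  cog <- simulate_cognate_set(92, d$genome, d$truth, n = 10,
                              vr_adenine_rate = 0.3, background_rate = 0.01)
  st <- msa_column_stats(cog$msa, "ref")

  shuffled <- cog$msa[c(1, sample(2:length(cog$msa)))]
  expect_equal(msa_column_stats(shuffled, "ref"), st)

  ## insert an all-gap column at position 100
  ins <- vapply(cog$msa, function(s) {
    paste0(substr(s, 1, 99), "-", substr(s, 100, nchar(s)))
  }, "")
  expect_equal(msa_column_stats(ins, "ref"), st)
})

test_that("variation and adenine tracks match brute-force window recomputation", {
  set.seed(95)
  for (rep in 1:10) {
    len <- sample(300:2000, 1)
    n <- sample(5:20, 1)
    msa <- setNames(c(rand_seq(len), vapply(seq_len(n - 1), function(i) {
      s <- rand_seq(len)
      s
    }, "")), c("ref", paste0("s", seq_len(n - 1))))
    st <- msa_column_stats(msa, "ref")
    bst <- brute_msa_stats(msa, "ref")
    expect_equal(st$variation, bst$variation)
    expect_equal(st$conserved, bst$conserved)
    expect_equal(st$conserved_A, bst$conserved_A)

    vt <- variation_track(st)
    w <- enumerate_windows(len, phage_window_spec())
    expect_equal(vt$variation, brute_window_mean(st$variation, w))

    at <- adenine_conservation_track(st)
    brute_pct <- vapply(seq_len(nrow(w)), function(i) {
      cons <- st$conserved[w$start[i]:w$end[i]]
      ca <- st$conserved_A[w$start[i]:w$end[i]]
      if (!sum(cons)) NA_real_ else 100 * sum(ca) / sum(cons)
    }, numeric(1))
    expect_equal(at$adenine_pct, brute_pct)
  }
})

test_that("adenine conservation: 12 A of 30 conserved columns gives 40 percent", {
  st <- data.frame(position = 1:30, variation = 0,
                   conserved = TRUE,
                   conserved_A = c(rep(TRUE, 12), rep(FALSE, 18)))
  at <- adenine_conservation_track(st, window_spec(30, 30, 0))
  expect_equal(at$adenine_pct, 40)
  st0 <- data.frame(position = 1:30, variation = 0.5,
                    conserved = FALSE, conserved_A = FALSE)
  expect_true(is.na(adenine_conservation_track(st0,
                                               window_spec(30, 30, 0))$adenine_pct))
})

test_that("pileup variation equals the per-position oracle", {
  p <- data.frame(A = c(90L, 0L), C = c(10L, 0L), G = 0L, T = 0L)
  v <- pileup_variation(p)
  expect_equal(v[1], 0.1)
  expect_true(is.na(v[2]))
  expect_error(pileup_variation(data.frame(A = -1L, C = 0L, G = 0L, T = 0L)),
               "negative")

  set.seed(101)
  for (rep in 1:10) {
    n <- sample(50:500, 1)
    pl <- data.frame(A = rpois(n, 20), C = rpois(n, 2), G = rpois(n, 2),
                     T = rpois(n, 1))
    pl[sample(n, 5), ] <- 0L
    expect_equal(pileup_variation(pl), brute_pileup_variation(pl))
  }
})

test_that("sample inclusion flips exactly at the depth/breadth boundaries", {
  mk <- function(n_deep, n_shallow, deep = 10L, shallow = 9L) {
    data.frame(A = c(rep(deep, n_deep), rep(shallow, n_shallow)),
               C = 0L, G = 0L, T = 0L)
  }
  expect_true(sample_inclusion(mk(95, 5))$include)     # breadth exactly 0.95
  expect_false(sample_inclusion(mk(94, 6))$include)
  expect_false(sample_inclusion(mk(0, 100))$include)   # depth 9 everywhere
  expect_true(sample_inclusion(mk(100, 0, deep = 1000L))$include)
})

test_that("activity calls separate planted from quiet variable repeats", {
  flat <- data.frame(start = seq(1, 1901, 20))
  flat$end <- flat$start + 100
  flat$variation <- 0.001
  ac <- vr_activity_call(flat, list(list(start = 500, end = 620)))
  expect_false(ac$active)
  expect_error(vr_activity_call(flat, list(list(start = 1, end = 99999)),
                                genome_len = 2001), "outside")

  set.seed(110)
  sens <- fp <- 0L
  n_runs <- 30L
  for (s in seq_len(n_runs)) {
    g <- setNames(rand_seq(4000), "ph")
    d <- plant_dgr(300L + s, g, tr_len = 120, n_vr = 1,
                   adenine_sub_count = 10)
    cog <- simulate_cognate_set(400L + s, d$genome, d$truth, n = 30,
                                vr_adenine_rate = 0.3,
                                background_rate = 0.002)
    st <- msa_column_stats(cog$msa, "ph")
    vt <- variation_track(st)
    sens <- sens + vr_activity_call(vt, d$truth$vrs)$active
    cog0 <- simulate_cognate_set(500L + s, d$genome, d$truth, n = 30,
                                 vr_adenine_rate = 0,
                                 background_rate = 0.002)
    vt0 <- variation_track(msa_column_stats(cog0$msa, "ph"))
    fp <- fp + vr_activity_call(vt0, d$truth$vrs)$active
  }
  expect_gte(sens / n_runs, 0.95)
  expect_lte(fp / n_runs, 0.05)
})

test_that("raising the VR substitution rate never lowers expected peak variation", {
  rates <- c(0.05, 0.1, 0.2, 0.4)
  set.seed(120)
  g <- setNames(rand_seq(3000), "ph")
  d <- plant_dgr(121, g, tr_len = 120, n_vr = 1, adenine_sub_count = 10)
  mean_peak <- vapply(rates, function(r) {
    peaks <- vapply(1:40, function(s) {
      cog <- simulate_cognate_set(1000L * s + round(1000 * r), d$genome,
                                  d$truth, n = 20, vr_adenine_rate = r,
                                  background_rate = 0.002)
      vt <- variation_track(msa_column_stats(cog$msa, "ph"))
      max(vt$variation, na.rm = TRUE)
    }, numeric(1))
    mean(peaks)
  }, numeric(1))
  expect_true(all(diff(mean_peak) > 0))
})
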