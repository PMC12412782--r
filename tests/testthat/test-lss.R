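test_that("bin_ratios normalizes treatment/reference bin sums", {
  g <- toy_gene("g", n = 8, start = 0)
  trt <- signal_track("g", c(0, 0, 0, 0, 2, 2, 2, 2), 8)
  ref <- signal_track("g", rep(1, 8), 8)
  # toy: m = 4, T bins (0,0,4,4), R bins (2,2,2,2), equal libs, pc 1
  prof <- bin_ratios(trt, ref, g, m = 4, pseudocount = 1)
  expect_equal(prof$values, c(1/3, 1/3, 5/3, 5/3))
  expect_equal(prof$bin_edges[, "start"], c(1, 3, 5, 7))
  expect_equal(prof$bin_edges[, "end"], c(2, 4, 6, 8))

  # identical tracks and libraries -> all ratios 1
  same <- bin_ratios(ref, ref, g, m = 4)
  expect_equal(same$values, rep(1, 4))

  # all-zero treatment with pseudocount -> strictly positive small ratios
  zero <- signal_track("g", numeric(8), 8)
  pz <- bin_ratios(zero, ref, g, m = 4, pseudocount = 1)
  expect_true(all(pz$values > 0 & pz$values < 1))

  expect_error(bin_ratios(trt, ref, g, m = 9), "exceeds")
})

test_that("bin tiling covers the gene without gaps; last bin absorbs", {
  for (n in c(40, 41, 1007, 40000)) {
    e <- bin_edges(n, 40)
    expect_equal(unname(e[1, "start"]), 1)
    expect_equal(unname(e[40, "end"]), n)
    expect_true(all(e[-1, "start"] == e[-40, "end"] + 1))
    expect_true(all(e[-40, 2] - e[-40, 1] + 1 == floor(n / 40)))
  }
})

test_that("ss_scan matches the brute-force contiguous 2-partition oracle", {
  # perfect step: split exactly at the step, score 0
  sc <- ss_scan(c(0, 0, 0, 1, 1, 1))
  expect_equal(sc$argmin, 3)
  expect_equal(sc$ss[3], 0)
  expect_equal(sc$n_candidates, 6)
  # constant vector: all scores 0, tie broken to the first pointer
  scc <- ss_scan(rep(0.7, 10))
  expect_equal(scc$ss, rep(0, 10))
  expect_equal(scc$argmin, 1)
  # seeded random vectors: exhaustive enumeration oracle
  set.seed(42)
  for (i in 1:20) {
    v <- rnorm(sample(2:50, 1), sd = runif(1, 0.1, 10))
    sc <- ss_scan(v)
    oracle <- brute_force_ss(v)
    expect_equal(sc$ss, oracle, tolerance = 1e-10)
    expect_equal(sc$argmin, which.min(oracle))
  }
  expect_error(ss_scan(1), "at least 2")
})

test_that("split score is nonnegative, zero iff both segments constant", {
  set.seed(5)
  for (i in 1:10) {
    v <- rnorm(30)
    expect_true(all(ss_scan(v)$ss >= 0))
  }
  stepv <- c(rep(2, 4), rep(5, 6))
  sc <- ss_scan(stepv)
  expect_equal(which(sc$ss == 0), 4)   # only the exact step is zero
})

test_that("candidate-count identities hold", {
  expect_equal(count_candidates(40000, 40), 2040)
  expect_equal(count_candidates(40000, 40, two_stage = FALSE), 40000)
  expect_equal(count_candidates(10, 10), 12)   # n = m: m + 2
})

test_that("split_significance uses exact, permutation and normal paths", {
  # (0,0,0 | 1,1,1): permutation-exact with midranks, p = 1/choose(6,3)
  expect_equal(split_significance(c(0, 0, 0, 1, 1, 1), 3), 0.05)
  # identical constant segments: no separation
  expect_gte(split_significance(rep(1, 10), 5), 0.5)
  # 20 zeros vs 20 ones: far beyond any alpha (normal approximation)
  expect_lt(split_significance(c(rep(0, 20), rep(1, 20)), 20), 1e-6)
  # no-ties exact path agrees with wilcox.test exact
  set.seed(2)
  v <- rnorm(12)
  expect_equal(split_significance(v, 5),
               wilcox.test(v[1:5], v[6:12], alternative = "less",
                           exact = TRUE)$p.value)
  # empty segment -> NA
  expect_true(is.na(split_significance(c(1, 2, 3), 3)))
})

test_that("stronger separation never weakens one-sided significance", {
  set.seed(9)
  base <- c(runif(15, 0, 0.3), runif(15, 0.5, 1))
  p_prev <- Inf
  for (c_mult in c(1, 2, 5, 20)) {
    v <- base
    v[16:30] <- v[16:30] * c_mult
    p <- split_significance(v, 15)
    expect_lte(p, p_prev + 1e-12)
    p_prev <- p
  }
})

test_that("refine_to_base recovers a clean step and reports the region", {
  g <- toy_gene("g", n = 4000, start = 0)
  # treatment: zero up to base 1940, uniform beyond; reference uniform
  truth <- 1940
  trt <- signal_track("g", c(numeric(truth), rep(2, g$n - truth)),
                      2 * (g$n - truth))
  ref <- signal_track("g", rep(2, g$n), 2 * g$n)
  prof <- bin_ratios(trt, ref, g, m = 10)
  tbin <- ss_scan(prof$values)$argmin
  r <- refine_to_base(trt, ref, g, tbin, m = 10)
  expect_equal(r$transition_base, truth)
  expect_lt(r$p_base, 1e-6)
  expect_equal(r$n_evals, r$region[2] - r$region[1] + 1)

  # constant region: argmin 1, not significant
  flat <- refine_to_base(ref, ref, g, 5, m = 10)
  expect_equal(flat$transition_base, unname(bin_edges(g$n, 10)[5, 1]))
  expect_gte(flat$p_base, 0.5)
})

test_that("two-stage and exhaustive single-stage agree on step signals", {
  # oracle equivalence on short genes with noiseless steps
  set.seed(21)
  agree <- vapply(1:20, function(i) {
    n <- sample(seq(400, 2000, by = 40), 1)
    truth <- sample(seq(40, n - 40), 1)
    g <- toy_gene(paste0("g", i), n = n, start = 0)
    trt <- signal_track(g$gene_id, c(numeric(truth), rep(3, n - truth)),
                        3 * (n - truth))
    ref <- signal_track(g$gene_id, rep(3, n), 3 * n)
    # single-stage: exhaustive base-level scan
    single <- ss_scan(((trt$counts + 1) / trt$library_size) /
                        ((ref$counts + 1) / ref$library_size))$argmin
    # two-stage
    tbin <- ss_scan(bin_ratios(trt, ref, g, m = 20)$values)$argmin
    two <- refine_to_base(trt, ref, g, tbin, m = 20)$transition_base
    two == single && single == truth
  }, logical(1))
  expect_true(all(agree))
})

test_that("rate arithmetic", {
  expect_equal(infer_rate(30000, 15), 2000)
  expect_equal(infer_rate(0, 15), 0)
  expect_equal(infer_rate(36300, 25), 1452)
})

test_that("infer_rates runs the full two-stage pipeline", {
  set.seed(33)
  ds <- simulate_dataset(sim_config(n_genes = 8, seed = 33))
  res <- infer_rates(ds$genes, ds$treatment_tracks, ds$reference_tracks,
                     rate_config())
  expect_setequal(
    colnames(res),
    c("gene_id", "chrom", "strand", "n", "method", "transition_bin",
      "transition_base", "p_bin", "q_bin", "p_base", "q_base",
      "significant", "rate_bp_per_min", "reference_fpkm"))
  expect_true(all(res$significant))
  expect_equal(res$rate_bp_per_min, res$transition_base / 15)
  # near-total depletion: rates approximate Distance * n / minutes
  expect_equal(res$transition_base,
               unname(ds$truth[res$gene_id]), tolerance = 0.01)

  # negative control: treatment = reference -> no significant calls
  res0 <- infer_rates(ds$genes, ds$reference_tracks, ds$reference_tracks,
                      rate_config())
  expect_equal(sum(res0$significant), 0)

  # no gene passes filters -> empty result with a warning
  expect_warning(
    empty <- infer_rates(ds$genes, ds$treatment_tracks,
                         ds$reference_tracks,
                         rate_config(min_length = 1e9)),
    "no genes")
  expect_equal(nrow(empty), 0)
})

test_that("split-score evaluations match the candidate-count identity", {
  # divisible gene lengths, interior transition: identity is exact
  set.seed(44)
  m <- 40
  for (n in c(40000, 48000)) {
    g <- toy_gene("g", n = n, start = 0)
    tr <- step_tracks(g, truth = round(0.4 * n), seed = n)
    res <- infer_rates(list(g),
                       list(g = tr$treatment), list(g = tr$reference),
                       rate_config(window_num = m))
    expect_equal(unname(attr(res, "n_ss_evals")),
                 count_candidates(n, m))
  }
})

test_that("one clean composite case: bin 18 then the in-region step", {
  m <- 40
  n <- 40000
  w <- n / m                       # 1000
  truth <- 18 * w - 250            # inside bin 18
  g <- toy_gene("g", n = n, start = 0)
  trt <- signal_track("g", c(numeric(truth), rep(2, n - truth)),
                      2 * (n - truth))
  ref <- signal_track("g", rep(2, n), 2 * n)
  prof <- bin_ratios(trt, ref, g, m = m)
  expect_equal(ss_scan(prof$values)$argmin, 18)
  r <- refine_to_base(trt, ref, g, 18, m = m)
  expect_equal(r$transition_base, truth)
})
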