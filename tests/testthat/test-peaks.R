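# Significance machinery and the three peak callers.

test_that("poisson_upper_tail matches the series oracle and edge cases", {
  expect_equal(poisson_upper_tail(0, 5), 1.0)
  expect_equal(poisson_upper_tail(1, 0), 0.0)
  expect_equal(poisson_upper_tail(0, 0), 1.0)
  # frozen from the series oracle: 1 - e^-1 (1 + 1 + 1/2)
  expect_equal(poisson_upper_tail(3, 1), 1 - exp(-1) * 2.5, tolerance = 1e-14)
  expect_error(poisson_upper_tail(-1, 1), "nonnegative")
  expect_error(poisson_upper_tail(1, -1), "nonnegative")
  for (lam in c(0.1, 1, 4.5, 17)) {
    for (x in c(0L, 1L, 3L, 10L, 35L)) {
      expect_equal(poisson_upper_tail(x, lam), oracle_poisson_tail(x, lam),
                   tolerance = 1e-13)
    }
  }
})

test_that("poisson_upper_tail is monotone in x and in lam", {
  lam <- 3.7
  p <- poisson_upper_tail(0:30, lam)
  expect_true(all(diff(p) <= 0))
  lams <- seq(0.1, 20, by = 0.5)
  p2 <- poisson_upper_tail(rep(4L, length(lams)), lams)
  expect_true(all(diff(p2) >= 0))
})

test_that("expected_count follows the with-background formula", {
  cfg <- caller_config(mode = "with_background", pseudocount = 0.5)
  # all ratios 1
  expect_equal(expected_count(cfg, ttaa_peak = 10, n_bkg_local = 10,
                              ttaa_local = 10, total_exp = 100,
                              total_bkg = 100), 10)
  # pseudocount floor
  expect_equal(expected_count(cfg, ttaa_peak = 5, n_bkg_local = 0,
                              ttaa_local = 5, total_exp = 100,
                              total_bkg = 100), 0.5)
  # local-lambda safeguard keeps the maximum over windows
  expect_equal(expected_count(cfg, ttaa_peak = 4, n_bkg_local = c(2, 40),
                              ttaa_local = c(4, 80), total_exp = 100,
                              total_bkg = 100),
               max(2 * 4 / 4, 40 * 4 / 80))
  expect_error(expected_count(cfg, ttaa_peak = 1, n_bkg_local = 1,
                              ttaa_local = 1, total_exp = 10, total_bkg = 0),
               "background_free")
})

test_that("expected_count follows the background-free formula", {
  cfg <- caller_config(mode = "background_free", pseudocount = 0.05)
  # 20 insertions in peak, 30 in window, ttaa_peak/window_ttaa = 1/100
  lam <- expected_count(cfg, ttaa_peak = 1, n_exp_peak = 20,
                        n_exp_windows = 30, ttaa_windows = 100)
  expect_equal(lam, 10 * 1 / 99, tolerance = 1e-12)
  # floored at pseudocount when the window adds nothing
  cfg2 <- caller_config(mode = "background_free", pseudocount = 0.5)
  expect_equal(expected_count(cfg2, ttaa_peak = 1, n_exp_peak = 20,
                              n_exp_windows = 20, ttaa_windows = 100), 0.5)
})

test_that("adjust_pvalues equals hand BH and p.adjust", {
  expect_equal(adjust_pvalues(0.01), 0.01)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  for (rep in 1:10) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_pvalues(p), oracle_bh(p))
    expect_equal(adjust_pvalues(p), stats::p.adjust(p, "BH"))
  }
})

test_that("CCcaller candidate blocks obey the gap rule and partition insertions", {
  ttaa <- uniform_ttaa(c(chrT = 20000L), spacing = 100L)
  s <- iset(c(100, 200, 5000))
  cfg <- candidate_cfg(maxbetween = 1000L)
  pk <- call_cccaller(s, NULL, ttaa, cfg)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$start, c(100L, 5000L))
  expect_equal(pk$end, c(204L, 5004L))
  expect_equal(pk$n_exp, c(2L, 1L))

  pk2 <- call_cccaller(s, NULL, ttaa, candidate_cfg(maxbetween = 5000L))
  expect_equal(nrow(pk2), 1L)

  # partition property on random data: block counts sum to the total
  set.seed(12)
  for (rep in 1:5) {
    pos <- sort(sample(0:19996, 200, replace = TRUE))
    si <- iset(pos)
    cand <- call_cccaller(si, NULL, ttaa, candidate_cfg(maxbetween = 300L))
    expect_equal(sum(cand$n_exp), si$total)
    # blocks are disjoint and separated by more than maxbetween
    expect_true(all(diff(cand$start) > 0))
  }
})

test_that("callers drop chromosomes absent from the TTAA index with a warning", {
  ttaa <- uniform_ttaa(c(chrT = 20000L))
  s <- InsertionSet(rbind(iset(c(100, 150, 180, 210, 240))$records,
                          iset(c(100, 150, 180, 210, 240), chrom = "chrZ")$records))
  expect_warning(pk <- call_cccaller(s, NULL, ttaa, candidate_cfg()), "chrZ")
  expect_true(all(pk$chrom == "chrT"))
})

test_that("identical inputs give byte-identical BED output", {
  cfg <- sim_config(seed = 5, n_true_peaks = 3L, n_background = 50L)
  sim <- simulate_insertions(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_bed(call_cccaller(sim$exp, sim$bkg, sim$ttaa), f1)
  sim2 <- simulate_insertions(sim_config(seed = 5, n_true_peaks = 3L,
                                         n_background = 50L))
  write_bed(call_cccaller(sim2$exp, sim2$bkg, sim2$ttaa), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 0L)
})

test_that("MACCs finds planted sites and separates distant ones", {
  # no insertions on a chromosome -> no peaks there
  ttaa <- uniform_ttaa(c(cA = 200000L, cB = 200000L), spacing = 250L)
  sim <- simulate_insertions(sim_config(
    chrom_lengths = c(cA = 200000L, cB = 200000L), n_true_peaks = 2L,
    centers = list(cA = c(50000L, 100000L)), n_background = 40L,
    min_separation = 10000L, seed = 21), ttaa = ttaa)
  only_a <- sim$truth$true_peaks$chrom
  pk <- call_maccs(sim$exp, sim$bkg, sim$ttaa, caller_config(window = 1000L))
  expect_true(all(unique(only_a) == "cA"))
  # no planted sites on cB -> no peaks called there
  expect_equal(nrow(pk[pk$chrom == "cB", ]), 0L)
  # two planted sites 50 kb apart -> two distinct merged candidates
  expect_equal(nrow(pk[pk$chrom == "cA", ]), 2L)
  sc <- score_caller(pk, sim$truth)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
})

test_that("CCcaller recovers a single planted site overlapping the truth", {
  sim <- simulate_insertions(sim_config(n_true_peaks = 1L, enrichment = 200,
                                        n_background = 100L, seed = 31))
  pk <- call_cccaller(sim$exp, sim$bkg, sim$ttaa)
  expect_equal(nrow(pk), 1L)
  tp <- sim$truth$true_peaks
  expect_true(pk$start < tp$end && tp$start < pk$end)
  pk_m <- call_maccs(sim$exp, sim$bkg, sim$ttaa)
  # CCcaller and MACCs peak sets overlap reciprocally
  expect_equal(nrow(pk_m), 1L)
  expect_true(pk_m$start < pk$end && pk$start < pk_m$end)
})

test_that("scaling both sets leaves the direction of enrichment unchanged", {
  sim <- simulate_insertions(sim_config(n_true_peaks = 2L, seed = 41,
                                        n_background = 100L))
  # pseudocount 0: the floor does not scale with library size, so the pure
  # scaling property only holds for the un-floored estimator
  cfg <- candidate_cfg(pseudocount = 0)
  base <- call_cccaller(sim$exp, sim$bkg, sim$ttaa, cfg)
  rep3 <- function(s) {
    r <- s$records[rep(seq_len(nrow(s$records)), each = 3L), ]
    InsertionSet(r)
  }
  scaled <- call_cccaller(rep3(sim$exp), rep3(sim$bkg), sim$ttaa, cfg)
  m <- merge(as.data.frame(base), as.data.frame(scaled),
             by = c("chrom", "start"))
  expect_gt(nrow(m), 0L)
  expect_equal(sign(m$n_exp.x - m$lam.x), sign(m$n_exp.y - m$lam.y))
})

test_that("Bayesian Blocks DP equals brute-force optimal segmentation (n <= 12)", {
  set.seed(99)
  for (rep in 1:12) {
    n <- sample(2:12, 1)
    pos <- sort(sample(1:500, n, replace = TRUE))
    ux <- unique(pos)
    w <- as.numeric(tabulate(match(pos, ux)))
    ncp <- 4 - log(73.53 * 0.05 * n^(-0.478))
    dp <- cckit:::bayesian_blocks_1d(ux, w, ncp)
    oracle <- oracle_bayesian_blocks(ux, w, ncp)
    expect_equal(segmentation_score(ux, w, dp$i, ncp), oracle$score,
                 tolerance = 1e-10)
  }
})

test_that("Blockify segments uniform events into one block, clusters into more", {
  ttaa <- uniform_ttaa(c(chrT = 100000L), spacing = 100L)
  set.seed(8)
  uni <- iset(sort(sample(seq(0L, 99996L, by = 100L), 12)))
  cfg <- candidate_cfg()
  pk <- call_blockify(uni, NULL, ttaa, cfg)
  expect_equal(nrow(pk), 1L)

  two <- iset(c(1000, 1100, 1150, 1200, 1300, 80000, 80050, 80100, 80200, 80300))
  pk2 <- call_blockify(two, NULL, ttaa, cfg)
  expect_gte(nrow(pk2), 2L)
  # a change point falls between the clusters
  expect_true(any(pk2$end <= 80000) && any(pk2$start >= 1300))

  # single insertion -> single width-4 testable block
  pk3 <- call_blockify(iset(5000L), NULL, ttaa, cfg)
  expect_equal(nrow(pk3), 1L)
  expect_equal(pk3$end - pk3$start, 4L)
  expect_true(pk3$pvalue >= 0 && pk3$pvalue <= 1)
})

test_that("caller_config validates its invariants", {
  expect_error(caller_config(step = 2000L, window = 1000L), "step")
  expect_error(caller_config(maxbetween = 0L), "maxbetween")
  expect_error(caller_config(lambda_windows = integer(0)), "lambda_windows")
  expect_error(call_cccaller(InsertionSet(), NULL, uniform_ttaa()), "empty")
})

test_that("an empty background falls back to background-free with a warning", {
  sim <- simulate_insertions(sim_config(n_true_peaks = 1L, enrichment = 100,
                                        n_background = 50L, seed = 77))
  expect_warning(pk <- call_cccaller(sim$exp, InsertionSet(), sim$ttaa),
                 "background-free|background_free")
  expect_gte(nrow(pk), 1L)
})
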