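# Peak matrices and differential binding tests.

test_that("assign_insertions respects the half-open boundary convention", {
  peaks <- pset("chrT", 100, 200)
  s <- iset(c(100, 150, 199, 200), barcode = "c1")
  m <- assign_insertions(s, peaks)
  expect_equal(as.numeric(m$counts[1, 1]), 3)   # 200 excluded
  expect_equal(unname(m$unassigned["c1"]), 1L)

  # no peaks: zero columns, everything unassigned
  m0 <- assign_insertions(s, PeakSet())
  expect_equal(ncol(m0$counts), 0L)
  expect_equal(sum(m0$unassigned), 4L)

  # identity-patterned 2x2
  peaks2 <- pset("chrT", c(100, 500), c(200, 600))
  s2 <- iset(c(150, 550), barcode = c("cellA", "cellB"))
  m2 <- assign_insertions(s2, peaks2)
  expect_equal(as.matrix(m2$counts)[, ], diag(2),
               ignore_attr = TRUE)

  expect_error(assign_insertions(iset(1), peaks), "barcode")
})

test_that("matrix column sums equal per-peak insertion totals", {
  sim <- simulate_insertions(sim_config(seed = 13, n_true_peaks = 4L,
                                        n_background = 100L, n_cells = 20L,
                                        n_clusters = 2L))
  pk <- call_cccaller(sim$exp, sim$bkg, sim$ttaa)
  m <- assign_insertions(sim$exp, pk)
  direct <- vapply(seq_len(nrow(pk)), function(i)
    sum(sim$exp$records$chrom == pk$chrom[i] &
          sim$exp$records$start >= pk$start[i] &
          sim$exp$records$start < pk$end[i]), numeric(1))
  expect_equal(unname(Matrix::colSums(m$counts)), direct)
  expect_equal(sum(m$counts) + sum(m$unassigned), sim$exp$total)
})

test_that("fisher_diff equals the enumeration oracle on frozen tables", {
  # [[3,1],[1,3]] -> 34/70 by full hypergeometric enumeration
  expect_equal(cckit:::fisher_twosided_p(3, 1, 1, 3), 34 / 70,
               tolerance = 1e-12)
  # identical rows -> 1
  expect_equal(cckit:::fisher_twosided_p(5, 95, 5, 95), 1)
  # extreme table vs oracle
  expect_equal(cckit:::fisher_twosided_p(0, 10, 10, 0),
               oracle_fisher(0, 10, 10, 0), tolerance = 1e-12)
  # random tables vs oracle and stats::fisher.test
  set.seed(5)
  for (rep in 1:25) {
    tab <- sample(0:12, 4, replace = TRUE)
    p <- cckit:::fisher_twosided_p(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p, oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    if (sum(tab) > 0) {
      ft <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
      expect_equal(p, ft, tolerance = 1e-9)
    }
  }
})

test_that("fisher_diff is symmetric with flipped direction", {
  peaks <- pset("chrT", c(0, 1000), c(500, 1500))
  a <- iset(c(rep(100, 30), rep(1200, 5)))
  b <- iset(c(rep(100, 10), rep(1200, 25)))
  m <- assign_insertions(list(A = a, B = b), peaks)
  ab <- fisher_diff(m, "A", "B")
  ba <- fisher_diff(m, "B", "A")
  expect_equal(ab$pvalue, ba$pvalue)
  expect_equal(ab$log2fc, -ba$log2fc)
  # peak 1 is A-enriched in both orientations (direction names the
  # enriched group; the fold-change sign flips)
  expect_equal(ab$direction[1], "A")
  expect_equal(ba$direction[1], "A")
  # conservation: n_in + n_out equals column totals
  expect_equal(ab$n_in + ab$n_out, unname(Matrix::colSums(m$counts)))
})

test_that("binomial_diff matches direct tail summation", {
  peaks <- pset("chrT", 0, 500)
  a <- iset(rep(100, 2)); b <- iset(rep(100, 2))
  m <- assign_insertions(list(A = a, B = b), peaks)
  d <- binomial_diff(m, "A")   # x = 2, n = 4, p0 = 0.5
  expect_equal(d$pvalue, oracle_binom_tail(2, 4, 0.5), tolerance = 1e-12)
  # frozen oracle values
  expect_equal(stats::pbinom(1, 2, 0.5, lower.tail = FALSE), 0.25)
  expect_equal(oracle_binom_tail(0, 5, 0.3), 1)
  expect_equal(stats::pbinom(6, 10, 0.3, lower.tail = FALSE),
               oracle_binom_tail(7, 10, 0.3), tolerance = 1e-12)
  expect_error(binomial_diff(m, "A", background_fraction = 1.5), "p0")
})

test_that("rank_peak_groups ranks by p then fold change, deterministically", {
  peaks <- pset("chrT", c(0, 1000, 2000), c(500, 1500, 2500))
  a <- iset(c(rep(100, 40), rep(1200, 5), rep(2200, 10)), barcode = "x")
  b <- iset(c(rep(100, 5), rep(1200, 40), rep(2200, 10)), barcode = "y")
  m <- assign_insertions(list(clustA = a, clustB = b), peaks)
  rk <- rank_peak_groups(m)
  expect_named(rk, c("clustA", "clustB"))
  expect_true(all(diff(rk$clustA$pvalue) >= 0))
  expect_equal(rk$clustA$peak[1], "chrT:0-500")
  expect_equal(rk$clustB$peak[1], "chrT:1000-1500")
})

test_that("joint strategy flags a group-specific site and is null on identical groups", {
  ttaa <- uniform_ttaa(c(chrT = 100000L), spacing = 200L)
  set.seed(17)
  bg_a <- sample(seq(0L, 99996L, 200L), 60, replace = TRUE)
  bg_b <- sample(seq(0L, 99996L, 200L), 60, replace = TRUE)
  site <- rep(50000L, 60) + sample(c(0L, 200L, 400L), 60, replace = TRUE)
  a <- iset(sort(c(bg_a, site)))
  b <- iset(sort(c(bg_b, sample(site, 6))))   # 10x less binding in B
  res <- diff_strategy_joint(list(A = a, B = b), ttaa,
                             caller_config(pvalue_cutoff = 0.01))
  hit <- res$results[res$results$padj <= 0.05, ]
  expect_gte(nrow(hit), 1L)
  expect_true(all(hit$direction == "A"))

  # identical groups: exchangeable, nothing significant
  res0 <- diff_strategy_joint(list(A = a, B = a), ttaa,
                              caller_config(pvalue_cutoff = 0.01))
  expect_true(all(res0$results$padj > 0.05))

  expect_error(diff_strategy_joint(list(A = a, B = InsertionSet()), ttaa),
               "no insertions")
})

test_that("separate strategy merges overlapping peaks into union intervals", {
  # construct two one-peak groups with shifted intervals via direct helpers
  pa <- pset("chrT", 100, 200)
  pb <- pset("chrT", 150, 250)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    c("chrT", "chrT"), IRanges::IRanges(c(101, 151), c(200, 250))))
  expect_equal(GenomicRanges::start(gr) - 1L, 100L)
  expect_equal(GenomicRanges::end(gr), 250L)

  # end to end: same planted site, slightly different sampling in each group
  ttaa <- uniform_ttaa(c(chrT = 100000L), spacing = 200L)
  set.seed(23)
  mk <- function(center) iset(sort(c(
    sample(seq(0L, 99996L, 200L), 40, replace = TRUE),
    center + sample(seq(-400L, 400L, 200L), 80, replace = TRUE))))
  res <- diff_strategy_separate(list(A = mk(50000L), B = mk(50200L)), ttaa,
                                caller_config(pvalue_cutoff = 0.01))
  expect_gte(nrow(res$peaks), 1L)
  # equal enrichment: the union peak is not significant
  un <- res$results[grepl("chrT:49", res$results$peak) |
                      grepl("chrT:5", res$results$peak), ]
  expect_true(all(un$pvalue > 0.05))
  # conservation across groups
  m <- res$matrix
  expect_equal(unname(Matrix::colSums(m$counts)),
               unname(Matrix::colSums(m$counts[1, , drop = FALSE]) +
                        Matrix::colSums(m$counts[2, , drop = FALSE])))
})

test_that("peak matrix serializes to MTX + TSV", {
  peaks <- pset("chrT", c(0, 1000), c(500, 1500))
  m <- assign_insertions(iset(c(100, 1200), barcode = c("a", "b")), peaks)
  d <- file.path(tempdir(), "pm")
  write_peak_matrix(m, d)
  expect_true(file.exists(file.path(d, "counts.mtx")))
  back <- Matrix::readMM(file.path(d, "counts.mtx"))
  expect_equal(as.matrix(back) * 1, as.matrix(m$counts), ignore_attr = TRUE)
})
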