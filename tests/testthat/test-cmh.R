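test_that("no frequency change gives statistic 0 and p = 1", {
  res <- cmh_test(a = c(30, 40, 50), b = c(10, 20, 30),
                  c = c(30, 40, 50), d = c(10, 20, 30), correction = FALSE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$neg_log10_p, 0)
})

test_that("single stratum matches the hand-evaluated Mantel-Haenszel closed form", {
  # (a,b,c,d) = (30,20,10,40): T=100, E[a]=50*40/100=20, dev=10,
  # V = 50*50*40*60/(100^2*99) = 600/99, stat = 100*99/600 = 16.5
  res <- cmh_test(30, 20, 10, 40, correction = FALSE)
  expect_equal(res$statistic, 16.5)
  expect_equal(res$p_value, pchisq(16.5, 1, lower.tail = FALSE))
})

test_that("statistic is invariant to allele-label swap and stratum permutation", {
  for (tab in random_tables(25, K = 3, seed = 5)) {
    base <- cmh_test(tab$a, tab$b, tab$c, tab$d)
    swap <- cmh_test(tab$b, tab$a, tab$d, tab$c)
    expect_equal(swap$statistic, base$statistic, tolerance = 1e-12)
    expect_equal(swap$p_value, base$p_value, tolerance = 1e-12)
    perm <- sample(3)
    permuted <- cmh_test(tab$a[perm], tab$b[perm], tab$c[perm], tab$d[perm])
    expect_equal(permuted$statistic, base$statistic, tolerance = 1e-12)
  }
})

test_that("cmh_test matches the independent reference implementation", {
  # 1000 random tables across K and continuity settings, >= 10 significant
  # digits against stats::mantelhaen.test
  configs <- expand.grid(K = c(1, 2, 3, 5), correct = c(TRUE, FALSE))
  n_each <- 125
  for (i in seq_len(nrow(configs))) {
    K <- configs$K[i]; correct <- configs$correct[i]
    for (tab in random_tables(n_each, K = K, seed = 100 + i)) {
      dev <- sum(tab$a - (tab$a + tab$b) * (tab$a + tab$c) /
                   (tab$a + tab$b + tab$c + tab$d))
      # the floored-at-zero regime |sum dev| <= 0.5 is asserted separately
      if (correct && abs(dev) <= 0.6) next
      ours <- cmh_test(tab$a, tab$b, tab$c, tab$d, correction = correct)
      ref <- mantelhaen_ref(tab, correction = correct)
      expect_equal(ours$statistic, ref$statistic, tolerance = 1e-10)
      expect_equal(ours$p_value, ref$p_value, tolerance = 1e-10)
    }
  }
})

test_that("continuity correction floors the statistic at zero", {
  # deviation sum below 0.5 cannot go negative-squared: statistic is 0
  tab <- list(a = c(20, 20), b = c(20, 20), c = c(20, 21), d = c(20, 20))
  dev <- sum(tab$a - (tab$a + tab$b) * (tab$a + tab$c) /
               (tab$a + tab$b + tab$c + tab$d))
  expect_lt(abs(dev), 0.5)
  res <- cmh_test(tab$a, tab$b, tab$c, tab$d, correction = TRUE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("zero-margin strata are dropped, not fatal", {
  # stratum 2 has an empty evolved sample (zero row margin)
  with_zero <- cmh_test(a = c(30, 5), b = c(20, 0), c = c(10, 0), d = c(40, 0),
                        correction = FALSE)
  only_first <- cmh_test(30, 20, 10, 40, correction = FALSE)
  expect_equal(with_zero$statistic, only_first$statistic)
  expect_equal(with_zero$n_strata_used, 1)
  # all strata degenerate -> undefined result
  res <- cmh_test(a = 5, b = 0, c = 3, d = 0)
  expect_true(is.na(res$statistic))
})

test_that("cmh_scan returns one result per site with frequencies", {
  labels <- c("F1", "F2", "E1", "E2")
  maj <- matrix(c(90, 85, 40, 45,
                  50, 55, 50, 52,
                  70, 72, 68, 71), 3, 4, byrow = TRUE,
                dimnames = list(NULL, labels))
  minr <- matrix(c(10, 15, 60, 55,
                   50, 45, 50, 48,
                   30, 28, 32, 29), 3, 4, byrow = TRUE)
  b <- make_biallelic(maj, minr, founder = c("F1", "F2"))
  res <- cmh_scan(b, c("F1", "F2"), c("E1", "E2"))
  expect_equal(nrow(res), 3)
  expect_equal(res$f0_1, maj[, 1] / (maj[, 1] + minr[, 1]))
  expect_equal(res$ft_2, maj[, 4] / (maj[, 4] + minr[, 4]))
  # strong consistent change at site 1 -> smallest p
  expect_equal(which.min(res$p_value), 1L)
  expect_equal(res$neg_log10_p, -log10(res$p_value), tolerance = 1e-10)
})

test_that("large counts do not overflow the variance product", {
  res <- cmh_test(a = c(40000, 41000), b = c(20000, 21000),
                  c = c(30000, 29000), d = c(30000, 31000))
  expect_true(is.finite(res$statistic))
  ref <- mantelhaen_ref(list(a = c(40000, 41000), b = c(20000, 21000),
                             c = c(30000, 29000), d = c(30000, 31000)),
                        correction = TRUE)
  expect_equal(res$statistic, ref$statistic, tolerance = 1e-10)
})

test_that("p-values are calibrated under pure sampling but inflate under drift", {
  # with negligible drift (huge Ne) the test is approximately uniform
  set.seed(17)
  n <- 20000
  p0 <- founder_spectrum_beta(n)
  # huge pools isolate read-level binomial sampling, the regime the CMH
  # test models exactly
  quiet <- neutral_cohort(p0, n, ne = 5e5, t = 60, replicates = 3,
                          coverage_founder = 259, coverage_evolved = 100,
                          pool_sizes = c(2e6, 2e6))
  pq <- cmh_test_bulk(quiet$a, quiet$b, quiet$c, quiet$d,
                      correction = FALSE)$p_value
  frac_quiet <- mean(pq < 0.05, na.rm = TRUE)
  expect_lt(abs(frac_quiet - 0.05), 0.015)
  # with realistic drift the test is anti-conservative: this motivates the
  # empirical cutoff
  drifty <- neutral_cohort(p0, n, ne = 285, t = 60, replicates = 3,
                           coverage_founder = 259, coverage_evolved = 100,
                           pool_sizes = c(2000, 2000))
  pd <- cmh_test_bulk(drifty$a, drifty$b, drifty$c, drifty$d,
                      correction = FALSE)$p_value
  expect_gt(mean(pd < 0.05, na.rm = TRUE), 0.15)
})
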