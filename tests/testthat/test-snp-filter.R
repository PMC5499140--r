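test_that("call_snps keeps sites polymorphic in at least one founder replicate", {
  labels <- c("F1", "F2", "E1")
  maj <- matrix(c(50, 50, 50,
                  50, 50, 50,
                  50, 50, 50), 3, 3, byrow = TRUE,
                dimnames = list(NULL, labels))
  minr <- matrix(c(0, 0, 10,   # monomorphic in all founders -> excluded
                   0, 3, 0,    # minor only in founder replicate 2 -> included
                   1, 0, 0),   # single read in F1 -> included at default
                 3, 3, byrow = TRUE)
  b <- make_biallelic(maj, minr, founder = c("F1", "F2"))
  out <- call_snps(b)
  expect_equal(n_sites(out), 2)
  expect_equal(attr(out, "removed"), 1)
  # raising the threshold drops the singleton
  out2 <- call_snps(b, min_minor_count = 2)
  expect_equal(n_sites(out2), 1)
})

test_that("call_snps emits exactly the constructed polymorphic sites", {
  labels <- c("F1", "F2", "E1")
  n <- 10
  maj <- matrix(60, n, 3, dimnames = list(NULL, labels))
  minr <- matrix(0, n, 3)
  poly <- c(2, 5, 9)
  minr[poly, 1] <- c(4, 1, 7)
  minr[c(3, 6), 3] <- 5  # polymorphic only in the evolved sample: not called
  b <- make_biallelic(maj, minr, founder = c("F1", "F2"))
  out <- call_snps(b)
  expect_equal(out$pos, b$pos[poly])
})

test_that("coverage thresholds use nearest-rank quantiles", {
  # single library, depths exactly 1..1000
  maj <- matrix(1:1000, 1000, 1, dimnames = list(NULL, "F1"))
  minr <- matrix(0, 1000, 1)
  minr[, 1] <- 0
  maj[, 1] <- 1:1000
  b <- make_biallelic(maj, minr, founder = "F1")
  th <- coverage_thresholds(b, quantile = 0.01)
  # independent sort-based oracle
  expect_equal(th$upper, sort(1:1000)[ceiling(0.99 * 1000)])
  expect_equal(th$lower, sort(1:1000)[ceiling(0.01 * 1000)])
  expect_equal(th$upper, 990)
  expect_equal(th$lower, 10)
  expect_equal(th$upper_basis, "F1")
})

test_that("constant coverage is flagged degenerate", {
  maj <- matrix(100, 50, 1, dimnames = list(NULL, "F1"))
  b <- make_biallelic(maj, matrix(0, 50, 1), founder = "F1")
  expect_warning(coverage_thresholds(b), "degenerate")
})

test_that("coverage filter removes sites at the tail thresholds", {
  labels <- c("F1", "E1")
  maj <- matrix(c(100, 100,
                  423, 100,
                  5, 5,
                  200, 150), 4, 2, byrow = TRUE,
                dimnames = list(NULL, labels))
  b <- make_biallelic(maj, matrix(1, 4, 2), founder = "F1")
  th <- structure(list(upper = 424, lower = 12, upper_basis = "F1",
                       lower_basis = "total coverage across all samples",
                       quantile = 0.01), class = "coverage_thresholds")
  out <- apply_coverage_filter(b, th)
  expect_equal(out$pos, b$pos[c(1, 4)])  # 424x basis removed; 12x total removed
  expect_equal(attr(out, "removed"), 2)
  # all-pass thresholds are the identity
  th$upper <- 1e6; th$lower <- 0
  expect_equal(n_sites(apply_coverage_filter(b, th)), 4)
})

test_that("mask_intervals follows BED half-open coordinates", {
  maj <- matrix(50, 3, 1, dimnames = list(NULL, "F1"))
  b <- make_biallelic(maj, matrix(5, 3, 1), founder = "F1",
                      chrom = rep("2L", 3), pos = c(99, 100, 101))
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("2L\t99\t100", bed)  # covers 1-based position 100 only
  out <- mask_intervals(b, bed)
  expect_equal(out$pos, c(99L, 101L))
  expect_equal(attr(out, "removed"), 1)
  # empty mask is the identity
  gr0 <- GenomicRanges::GRanges()
  expect_equal(n_sites(mask_intervals(b, gr0)), 3)
})

test_that("mask_intervals agrees with a brute-force point-in-interval oracle", {
  set.seed(42)
  n <- 300
  pos <- sample.int(5000, n)
  maj <- matrix(50, n, 1, dimnames = list(NULL, "F1"))
  b <- make_biallelic(maj, matrix(5, n, 1), founder = "F1",
                      chrom = rep("2L", n), pos = sort(pos))
  starts0 <- sort(sample.int(4900, 20))  # 0-based BED starts
  ends0 <- starts0 + sample.int(80, 20)
  mask <- GenomicRanges::GRanges("2L", IRanges::IRanges(starts0 + 1, ends0))
  out <- mask_intervals(b, mask)
  inside <- vapply(b$pos, function(p) any(p > starts0 & p <= ends0), logical(1))
  expect_equal(out$pos, b$pos[!inside])
})

test_that("mask and coverage filters commute", {
  s <- make_random_sync(n = 60, n_samples = 3, seed = 21)
  b <- polarize(s, c("s1", "s2"))
  th <- structure(list(upper = 120, lower = 150, upper_basis = "s1",
                       lower_basis = "total coverage across all samples",
                       quantile = 0.01), class = "coverage_thresholds")
  mask <- GenomicRanges::GRanges(c("2L", "2R"),
                                 IRanges::IRanges(c(1, 1), c(5e5, 5e5)))
  ab <- mask_intervals(apply_coverage_filter(b, th), mask)
  ba <- apply_coverage_filter(mask_intervals(b, mask), th)
  expect_equal(ab$pos, ba$pos)
  expect_equal(ab$major_counts, ba$major_counts)
})

test_that("filter tallies account for every removed site", {
  s <- make_random_sync(n = 100, n_samples = 3, seed = 31)
  b <- polarize(s, c("s1", "s2"))
  called <- call_snps(b)
  th <- coverage_thresholds(called, 0.05)
  filtered <- apply_coverage_filter(called, th)
  mask <- GenomicRanges::GRanges("2L", IRanges::IRanges(1, 3e5))
  masked <- mask_intervals(filtered, mask)
  expect_equal(n_sites(b) - n_sites(masked),
               attr(called, "removed") + attr(filtered, "removed") +
                 attr(masked, "removed"))
  rep <- filter_report(snp_call = called, coverage = filtered, mask = masked)
  expect_equal(rep$remaining[3], n_sites(masked))
})

test_that("binomial thinning halves coverage and preserves frequencies", {
  set.seed(7)
  n <- 1e5
  maj <- matrix(rpois(n, 70), n, 1, dimnames = list(NULL, "F1"))
  minr <- matrix(rpois(n, 30), n, 1)
  b <- make_biallelic(maj, minr, founder = "F1")
  cur <- mean(biallelic_coverage(b))
  out <- downsample_counts(b, cur / 2, seed = 1)
  expect_lt(abs(mean(biallelic_coverage(out)) / (cur / 2) - 1), 0.01)
  # expected allele frequency unchanged
  f_in <- sum(b$minor_counts) / sum(b$major_counts + b$minor_counts)
  f_out <- sum(out$minor_counts) / sum(out$major_counts + out$minor_counts)
  expect_lt(abs(f_out - f_in), 0.005)
})

test_that("thinning with ratio 1 is the identity and overshoot errors", {
  maj <- matrix(50, 10, 1, dimnames = list(NULL, "F1"))
  b <- make_biallelic(maj, matrix(10, 10, 1), founder = "F1")
  cur <- mean(biallelic_coverage(b))
  out <- downsample_counts(b, cur, seed = 1)
  expect_identical(out$major_counts, b$major_counts)
  expect_identical(out$minor_counts, b$minor_counts)
  expect_error(downsample_counts(b, cur + 1), "exceeds")
})
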