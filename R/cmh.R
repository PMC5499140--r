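# Cochran-Mantel-Haenszel test for replicated allele-frequency change
#
# Strata are experimental replicates; each stratum is the 2x2 table
# allele (major/minor) x time point (founder/evolved). The statistic is the
# 1-df Mantel-Haenszel chi-square
#   ((|sum_k (a_k - E[a_k])| - c)^2) / sum_k V_k
# with E[a_k] = n1k * m1k / Tk and
# V_k = n1k * n2k * m1k * m2k / (Tk^2 (Tk - 1)), c = 0.5 with the continuity
# correction. Strata with a zero row or column margin carry no information
# and are dropped from the sums; a site where all strata are degenerate
# yields an NA result and is excluded downstream.

# vectorized core over site matrices (sites x replicates)
.cmh_core <- function(a, b, c_, d, correction = TRUE) {
  # double arithmetic: margin products overflow 32-bit integers
  storage.mode(a) <- storage.mode(b) <- "double"
  storage.mode(c_) <- storage.mode(d) <- "double"
  Tk <- a + b + c_ + d
  n1 <- a + b; n2 <- c_ + d; m1 <- a + c_; m2 <- b + d
  ok <- n1 > 0 & n2 > 0 & m1 > 0 & m2 > 0
  dev <- ifelse(ok, a - n1 * m1 / Tk, 0)
  V <- ifelse(ok, n1 * n2 * m1 * m2 / (Tk^2 * (Tk - 1)), 0)
  sum_dev <- rowSums(dev)
  sum_V <- rowSums(V)
  cc <- if (correction) 0.5 else 0
  stat <- pmax(abs(sum_dev) - cc, 0)^2 / sum_V
  n_used <- rowSums(ok)
  stat[sum_V == 0] <- NA_real_
  log_p <- stats::pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE)
  neg_log10_p <- -log_p / log(10)
  p <- pmax(exp(log_p), .Machine$double.xmin)
  list(statistic = stat, p_value = p, neg_log10_p = neg_log10_p,
       n_strata_used = n_used)
}

#' Cochran-Mantel-Haenszel test on a single replicated 2x2 table
#'
#' @param a,b major- and minor-allele read counts in the founder sample, one
#'   entry per replicate.
#' @param c,d major- and minor-allele read counts in the evolved sample.
#' @param correction apply the 0.5 continuity correction (default `TRUE`,
#'   matching the conventional R-style Mantel-Haenszel test).
#' @return list with `statistic` (1-df chi-square; `NA` when every stratum
#'   has a zero margin), `p_value` (floored at the smallest positive double),
#'   `neg_log10_p`, and `n_strata_used`.
#' @examples
#' cmh_test(a = c(30), b = c(20), c = c(10), d = c(40), correction = FALSE)
#' @export
cmh_test <- function(a, b, c, d, correction = TRUE) {
  K <- length(a)
  stopifnot(K >= 1, length(b) == K, length(c) == K, length(d) == K,
            all(c(a, b, c, d) >= 0))
  res <- .cmh_core(matrix(a, 1), matrix(b, 1), matrix(c, 1), matrix(d, 1),
                   correction)
  lapply(res, `[[`, 1)
}

#' Genome scan with the CMH test
#'
#' Runs the CMH test at every site of a polarized count object, contrasting
#' paired founder and evolved replicates.
#'
#' @param x a `biallelic` object.
#' @param founder_samples,evolved_samples sample labels; replicate `k` pairs
#'   `founder_samples[k]` with `evolved_samples[k]`.
#' @param correction continuity correction flag, see [cmh_test()].
#' @return data.frame with chrom, pos, major, minor, per-replicate founder
#'   (`f0_k`) and evolved (`ft_k`) major-allele frequencies, `statistic`,
#'   `p_value` and `neg_log10_p` (`NA` for sites where every stratum was
#'   degenerate). Attributes `"n_undefined"` and `"n_strata_skipped"` report
#'   the skip tallies.
#' @export
cmh_scan <- function(x, founder_samples = x$founder_samples, evolved_samples,
                     correction = TRUE) {
  stopifnot(inherits(x, "biallelic"),
            length(founder_samples) == length(evolved_samples))
  fi <- match(founder_samples, x$sample_labels)
  ei <- match(evolved_samples, x$sample_labels)
  if (anyNA(fi) || anyNA(ei)) .stopf("unknown sample label in pairing")
  a <- x$major_counts[, fi, drop = FALSE]
  b <- x$minor_counts[, fi, drop = FALSE]
  cc <- x$major_counts[, ei, drop = FALSE]
  d <- x$minor_counts[, ei, drop = FALSE]
  res <- .cmh_core(a, b, cc, d, correction)
  K <- length(fi)
  out <- data.frame(chrom = x$chrom, pos = x$pos, major = x$major,
                    minor = x$minor, stringsAsFactors = FALSE)
  f0 <- a / (a + b)
  ft <- cc / (cc + d)
  for (k in seq_len(K)) out[[paste0("f0_", k)]] <- f0[, k]
  for (k in seq_len(K)) out[[paste0("ft_", k)]] <- ft[, k]
  out$statistic <- res$statistic
  out$p_value <- res$p_value
  out$neg_log10_p <- res$neg_log10_p
  out$p_value[is.na(res$statistic)] <- NA_real_
  out$neg_log10_p[is.na(res$statistic)] <- NA_real_
  attr(out, "n_undefined") <- sum(is.na(res$statistic))
  attr(out, "n_strata_skipped") <- sum(K - res$n_strata_used)
  out
}

#' CMH test on raw count matrices
#'
#' Bulk interface used for simulated cohorts: the four cell counts are given
#' directly as `sites x replicates` matrices.
#'
#' @param a,b founder major/minor read counts (`sites x K` matrices).
#' @param c,d evolved major/minor read counts.
#' @param correction continuity correction flag.
#' @return data.frame with `statistic`, `p_value`, `neg_log10_p`,
#'   `n_strata_used`.
#' @export
cmh_test_bulk <- function(a, b, c, d, correction = TRUE) {
  stopifnot(is.matrix(a), all(dim(a) == dim(b)), all(dim(a) == dim(c)),
            all(dim(a) == dim(d)))
  res <- .cmh_core(a, b, c, d, correction)
  data.frame(statistic = res$statistic, p_value = res$p_value,
             neg_log10_p = res$neg_log10_p, n_strata_used = res$n_strata_used)
}
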