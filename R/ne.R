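# Temporal effective population size from founder/evolved allele frequencies
#
# Moment-based (Fc) estimation in windows of consecutive SNPs, with a
# two-stage (pool, then reads) sampling correction appropriate for Pool-Seq
# and a plan-I census term for sampling designs where sequenced individuals
# are drawn from the breeding population.
#
# Per SNP, with founder read frequency x and evolved read frequency y,
#   Fc = (x - y)^2 / (z - x*y),  z = (x + y) / 2.
# Per window the drift signal is isolated as a ratio of sums
#   F = sum (x - y)^2 / sum (z - x*y)
# (heterozygosity-weighted, which removes the strong upward bias of averaging
# per-SNP ratios under a rare-variant-skewed spectrum), the expected sampling
# contribution mean(1/S0~) + mean(1/St~) is subtracted (S~ in chromosomes,
# 1/S~ = 1/S + 1/R - 1/(S*R) for pool size S and read depth R), the plan-I
# census term 1/(2*N_census) is added, and Ne solves the exact drift decay
#   F_drift = 1 - (1 - 1/(2*Ne))^t .

#' Standardized squared allele-frequency change (Fc)
#'
#' @param x founder allele frequency (reads of one allele / total reads).
#' @param y evolved allele frequency on the same axis.
#' @return `(x - y)^2 / (z - x*y)` with `z = (x + y)/2`; `NA` where the
#'   denominator is zero (site fixed for the same allele at both ends).
#'   Vectorized; symmetric under `(x, y) -> (1-x, 1-y)`.
#' @examples
#' fc_statistic(0.5, 0.6)  # 0.04
#' @export
fc_statistic <- function(x, y) {
  stopifnot(all(x >= 0 & x <= 1, na.rm = TRUE),
            all(y >= 0 & y <= 1, na.rm = TRUE))
  z <- (x + y) / 2
  den <- z - x * y
  ifelse(den > 0, (x - y)^2 / den, NA_real_)
}

#' Effective chromosome sample size of two-stage Pool-Seq sampling
#'
#' Pooling S chromosomes and then sequencing to depth R gives allele-frequency
#' sampling variance `p(1-p) * (1/S + 1/R - 1/(S*R))`; the effective sample
#' size is the reciprocal of that factor.
#'
#' @param S pool size in chromosomes.
#' @param R read depth.
#' @return effective sample size in chromosomes (vectorized).
#' @export
pool_seq_sample_size <- function(S, R) {
  stopifnot(all(S >= 2), all(R >= 1))
  1 / (1 / S + 1 / R - 1 / (S * R))
}

#' Estimate Ne from one window of SNPs
#'
#' @param x,y founder and evolved allele read frequencies (numeric vectors,
#'   one entry per SNP).
#' @param R0,Rt read depths at the two time points (vectors or scalars).
#' @param S0,St pool sizes in chromosomes at the two time points.
#' @param t generations elapsed between the two samples.
#' @param census census size in diploid individuals (plan I only).
#' @param plan `"I"` (sampled individuals drawn from the breeding population;
#'   adds the census term) or `"II"`.
#' @param min_snps minimum usable SNPs; fewer returns `NA`.
#' @return point estimate of Ne in diploid individuals, or `NA` when the
#'   corrected drift signal is non-positive (infinite-Ne signal) or the
#'   window is too small. Attribute `"n_used"` carries the usable SNP count.
#' @export
estimate_ne_window <- function(x, y, R0, Rt, S0, St, t, census = NULL,
                               plan = c("I", "II"), min_snps = 1) {
  plan <- match.arg(plan)
  stopifnot(t >= 1, length(x) == length(y))
  if (plan == "I" && is.null(census)) .stopf("plan I requires a census size")
  n <- length(x)
  R0 <- rep_len(R0, n); Rt <- rep_len(Rt, n)
  z <- (x + y) / 2
  den <- z - x * y
  use <- which(den > 0)
  est <- NA_real_
  if (length(use) >= min_snps) {
    F_ratio <- sum((x[use] - y[use])^2) / sum(den[use])
    c0 <- mean(1 / pool_seq_sample_size(S0, R0[use]))
    ct <- mean(1 / pool_seq_sample_size(St, Rt[use]))
    f_drift <- F_ratio - c0 - ct
    if (plan == "I") f_drift <- f_drift + 1 / (2 * census)
    if (f_drift > 0 && f_drift < 1) {
      est <- 1 / (2 * (1 - (1 - f_drift)^(1 / t)))
    }
  }
  attr(est, "n_used") <- length(use)
  est
}

#' Windowed Ne scan over a polarized count object
#'
#' Splits each chromosome's SNPs (in genomic order) into consecutive windows
#' of `window_snps` sites and estimates Ne per window and replicate. Trailing
#' windows with fewer than `min_window_snps` SNPs are dropped.
#'
#' @param x a `biallelic` object.
#' @param founder_samples,evolved_samples paired replicate labels.
#' @param t generations between the time points.
#' @param pool_sizes length-2 numeric, chromosomes pooled at the founder and
#'   evolved time points.
#' @param census census size in diploids (plan I).
#' @param window_snps SNPs per window (default 1000).
#' @param min_window_snps minimum SNPs for a trailing window; default half of
#'   `window_snps`.
#' @param plan sampling plan, see [estimate_ne_window()].
#' @return data.frame: chrom, window, start, end, n_snps, replicate, ne_hat
#'   (`NA` = undefined / infinite-Ne sentinel).
#' @export
ne_scan <- function(x, founder_samples = x$founder_samples, evolved_samples,
                    t, pool_sizes, census = NULL, window_snps = 1000,
                    min_window_snps = floor(window_snps / 2),
                    plan = c("I", "II")) {
  plan <- match.arg(plan)
  stopifnot(inherits(x, "biallelic"), length(pool_sizes) == 2,
            length(founder_samples) == length(evolved_samples))
  fi <- match(founder_samples, x$sample_labels)
  ei <- match(evolved_samples, x$sample_labels)
  if (anyNA(fi) || anyNA(ei)) .stopf("unknown sample label in pairing")
  out <- list()
  for (chr in unique(x$chrom)) {
    idx <- which(x$chrom == chr)
    idx <- idx[order(x$pos[idx])]
    nwin <- ceiling(length(idx) / window_snps)
    for (w in seq_len(nwin)) {
      wi <- idx[((w - 1) * window_snps + 1):min(w * window_snps, length(idx))]
      if (length(wi) < min_window_snps) next
      for (k in seq_along(fi)) {
        a <- x$major_counts[wi, fi[k]]; b <- x$minor_counts[wi, fi[k]]
        cc <- x$major_counts[wi, ei[k]]; d <- x$minor_counts[wi, ei[k]]
        R0 <- a + b; Rt <- cc + d
        ok <- R0 > 0 & Rt > 0
        est <- estimate_ne_window(
          x = (a / R0)[ok], y = (cc / Rt)[ok], R0 = R0[ok], Rt = Rt[ok],
          S0 = pool_sizes[1], St = pool_sizes[2], t = t, census = census,
          plan = plan)
        out[[length(out) + 1]] <- data.frame(
          chrom = chr, window = w, start = min(x$pos[wi]),
          end = max(x$pos[wi]), n_snps = length(wi),
          replicate = founder_samples[k], ne_hat = as.numeric(est),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Aggregate window Ne estimates
#'
#' The per-replicate summary is the median of defined window estimates; the
#' aggregate is the arithmetic mean of the replicate medians ("averaging the
#' medians across replicates").
#'
#' @param windows data.frame with columns `replicate` and `ne_hat`
#'   (as from [ne_scan()]), or any data.frame-like with those columns.
#' @return list with `ne` (aggregate), `replicate_medians` (named vector),
#'   and `n_undefined` (windows excluded from the medians).
#' @export
aggregate_ne <- function(windows) {
  stopifnot(all(c("replicate", "ne_hat") %in% names(windows)))
  meds <- tapply(windows$ne_hat, windows$replicate,
                 function(v) stats::median(v, na.rm = TRUE))
  list(ne = mean(meds), replicate_medians = c(meds),
       n_undefined = sum(is.na(windows$ne_hat)))
}
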