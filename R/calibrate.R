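# Empirical significance cutoff from a neutral cohort
#
# The CMH test does not account for drift, so its p-values are anti-
# conservative in an E&R contrast. The cutoff is therefore calibrated
# empirically: simulate a matched neutral cohort, take the -log10 p value
# above which only the nominal false-positive fraction of neutral SNPs falls,
# and call observed SNPs strictly above it.

#' Empirical -log10 p cutoff at a nominal false-positive rate
#'
#' The cutoff is the smallest cohort value `c` such that the fraction of the
#' cohort strictly above `c` is at most `fpr` (nearest-rank from above, so it
#' is reproducible with ties). Candidates are SNPs with `-log10 p` strictly
#' above the cutoff.
#'
#' @param neg_log10_p neutral-cohort `-log10 p` values; `NA` (undefined
#'   tests) are dropped.
#' @param fpr nominal false-positive rate, default 0.02.
#' @return list of class `"cutoff_result"`: `cutoff`, `fpr`, `n_neutral`.
#'   Warns when the cohort has fewer than `50 / fpr` values.
#' @export
empirical_cutoff <- function(neg_log10_p, fpr = 0.02) {
  stopifnot(fpr > 0, fpr < 1)
  x <- neg_log10_p[!is.na(neg_log10_p)]
  n <- length(x)
  if (n == 0) .stopf("empty neutral cohort")
  if (n < 50 / fpr) {
    .warnf("neutral cohort of %d is small for fpr = %g (recommend >= %d)",
           n, fpr, ceiling(50 / fpr))
  }
  u <- sort(unique(x))
  # fraction strictly above each unique value, decreasing in u
  n_le <- cumsum(tabulate(match(sort(x), u), nbins = length(u)))
  frac_above <- (n - n_le) / n
  cutoff <- u[which(frac_above <= fpr)[1]]
  structure(list(cutoff = cutoff, fpr = fpr, n_neutral = n),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("empirical cutoff: -log10 p > %.4f (nominal FPR %g, cohort n = %d)\n",
              x$cutoff, x$fpr, x$n_neutral))
  invisible(x)
}

#' Call candidate SNPs above an empirical cutoff
#'
#' @param observed a [cmh_scan()] result (or any data.frame with a
#'   `neg_log10_p` column).
#' @param cutoff numeric `-log10 p` threshold or a [empirical_cutoff()]
#'   result; candidacy is strict (`neg_log10_p > cutoff`).
#' @return the candidate subset in the original (genomic) order, with
#'   attribute `"n_tested"`.
#' @export
call_candidates <- function(observed, cutoff) {
  if (inherits(cutoff, "cutoff_result")) cutoff <- cutoff$cutoff
  stopifnot(is.numeric(cutoff), "neg_log10_p" %in% names(observed))
  keep <- !is.na(observed$neg_log10_p) & observed$neg_log10_p > cutoff
  out <- observed[keep, , drop = FALSE]
  attr(out, "n_tested") <- sum(!is.na(observed$neg_log10_p))
  out
}
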