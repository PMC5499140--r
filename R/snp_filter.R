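# SNP calling and count-level filtering
#
# Reproduces the standard E&R filtering chain on polarized counts: keep sites
# polymorphic in at least one founder replicate, trim the coverage-distribution
# tails, mask intervals (repeats, indel flanks, ...), and optionally thin
# counts to a target mean coverage. Each filter attaches the number of sites
# it removed as attribute "removed" so tallies can be reconciled.

#' Call SNPs from founder replicates
#'
#' A site is kept when at least one founder replicate individually shows at
#' least `min_minor_count` reads of the minor allele ("present in at least one
#' replicate"). Base-quality screening is assumed to have happened upstream of
#' the count files.
#'
#' @param x a `biallelic` object (see [polarize()]).
#' @param min_minor_count minimum minor-allele reads in a single founder
#'   replicate; default 1.
#' @return the filtered `biallelic` object, with attribute `"removed"` giving
#'   the number of excluded sites.
#' @export
call_snps <- function(x, min_minor_count = 1) {
  stopifnot(inherits(x, "biallelic"), min_minor_count >= 1)
  fidx <- match(x$founder_samples, x$sample_labels)
  minc <- x$minor_counts[, fidx, drop = FALSE]
  keep <- apply(minc >= min_minor_count, 1, any)
  out <- x[keep]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Coverage-tail thresholds
#'
#' Computes the removal thresholds for the upper and lower tails of the
#' coverage distribution: the upper threshold is the `1 - quantile`
#' nearest-rank quantile of per-site coverage in the single library with the
#' highest mean depth; the lower threshold is the `quantile` nearest-rank
#' quantile of per-site total coverage summed over all samples. Sites with
#' basis-library depth at or above the upper threshold, or total depth at or
#' below the lower threshold, are removed by [apply_coverage_filter()].
#'
#' @param x a `biallelic` object.
#' @param quantile tail mass on each side; default 0.01.
#' @return a list of class `"coverage_thresholds"` with `upper`, `lower`,
#'   `upper_basis` (label of the deepest library), `lower_basis`, `quantile`.
#' @export
coverage_thresholds <- function(x, quantile = 0.01) {
  stopifnot(inherits(x, "biallelic"), quantile > 0, quantile < 0.5)
  if (n_sites(x) == 0) .stopf("cannot compute coverage thresholds on 0 sites")
  cov <- biallelic_coverage(x)
  basis <- which.max(colMeans(cov))
  upper <- nearest_rank_quantile(cov[, basis], 1 - quantile)
  lower <- nearest_rank_quantile(rowSums(cov), quantile)
  if (!any(cov[, basis] < upper & rowSums(cov) > lower)) {
    .warnf("degenerate coverage thresholds (upper %d, lower %d): all sites would be removed",
           upper, lower)
  }
  structure(list(upper = upper, lower = lower,
                 upper_basis = x$sample_labels[basis],
                 lower_basis = "total coverage across all samples",
                 quantile = quantile),
            class = "coverage_thresholds")
}

#' @export
print.coverage_thresholds <- function(x, ...) {
  cat(sprintf("coverage thresholds: remove >= %dx in '%s', <= %dx total (q = %g)\n",
              x$upper, x$upper_basis, x$lower, x$quantile))
  invisible(x)
}

#' Remove coverage-tail sites
#'
#' @param x a `biallelic` object.
#' @param thresholds a [coverage_thresholds()] result.
#' @return filtered `biallelic` with attribute `"removed"`.
#' @export
apply_coverage_filter <- function(x, thresholds) {
  stopifnot(inherits(x, "biallelic"), inherits(thresholds, "coverage_thresholds"))
  cov <- biallelic_coverage(x)
  basis <- match(thresholds$upper_basis, x$sample_labels)
  if (is.na(basis)) .stopf("threshold basis library '%s' not in data",
                           thresholds$upper_basis)
  keep <- cov[, basis] < thresholds$upper & rowSums(cov) > thresholds$lower
  out <- x[keep]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Mask sites falling in BED intervals
#'
#' Drops sites whose 1-based position lies in any masked interval. Masks are
#' BED-convention 0-based half-open; a BED record `chr 99 100` covers the
#' 1-based position 100.
#'
#' @param x a `biallelic` object.
#' @param mask a `GRanges` of masked intervals, or a path to a BED file
#'   (read with `rtracklayer::import`, which performs the coordinate
#'   conversion).
#' @return filtered `biallelic` with attribute `"removed"`.
#' @export
mask_intervals <- function(x, mask) {
  stopifnot(inherits(x, "biallelic"))
  if (is.character(mask)) mask <- rtracklayer::import(mask, format = "BED")
  if (n_sites(x) == 0 || length(mask) == 0) {
    attr(x, "removed") <- 0L
    return(x)
  }
  sites <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos))
  hit <- IRanges::overlapsAny(sites, mask)
  out <- x[!hit]
  attr(out, "removed") <- sum(hit)
  out
}

#' Binomially thin counts to a target mean coverage
#'
#' Count-level analogue of read downsampling: within each sample, every
#' allele count (major, minor, and dropped mass) is thinned binomially with
#' probability `target_mean_coverage / mean coverage of that sample`, so the
#' expected allele frequency at every site is unchanged and libraries end up
#' with similar mean genome-wide coverage.
#'
#' @param x a `biallelic` object.
#' @param target_mean_coverage desired mean per-site coverage; must not
#'   exceed the current mean of any sample.
#' @param seed optional integer seed.
#' @return a `biallelic` object with thinned counts.
#' @export
downsample_counts <- function(x, target_mean_coverage, seed = NULL) {
  stopifnot(inherits(x, "biallelic"), target_mean_coverage > 0)
  .maybe_seed(seed)
  cov <- biallelic_coverage(x)
  means <- colMeans(cov)
  if (any(target_mean_coverage > means)) {
    .stopf("target mean coverage %.1f exceeds current mean of sample(s): %s",
           target_mean_coverage,
           paste(x$sample_labels[target_mean_coverage > means], collapse = ", "))
  }
  ratio <- target_mean_coverage / means
  thin <- function(m) {
    for (j in seq_along(ratio)) {
      if (ratio[j] < 1) m[, j] <- stats::rbinom(nrow(m), m[, j], ratio[j])
    }
    m
  }
  x$major_counts <- thin(x$major_counts)
  x$minor_counts <- thin(x$minor_counts)
  x$dropped <- thin(x$dropped)
  x
}

#' Summarize a chain of filters
#'
#' @param ... named filtered `biallelic` objects carrying `"removed"`
#'   attributes, in application order.
#' @return data.frame with one row per filter: name, sites removed, sites
#'   remaining.
#' @export
filter_report <- function(...) {
  steps <- list(...)
  data.frame(filter = names(steps),
             removed = vapply(steps, function(s) as.integer(attr(s, "removed") %||% NA),
                              integer(1)),
             remaining = vapply(steps, n_sites, integer(1)),
             stringsAsFactors = FALSE)
}
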