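# internal helpers

#' Nearest-rank quantile
#'
#' Deterministic quantile for integer-valued data: the value at rank
#' `ceiling(p * n)` of the sorted vector. Used for coverage-tail thresholds.
#'
#' @param x numeric vector, non-empty.
#' @param p probability in (0, 1].
#' @return a single element of `x`.
#' @keywords internal
nearest_rank_quantile <- function(x, p) {
  stopifnot(length(x) > 0, is.numeric(p), length(p) == 1, p > 0, p <= 1)
  sort(x)[ceiling(p * length(x))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# set.seed only when the caller supplied one
.maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
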