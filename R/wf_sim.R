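# Forward Wright-Fisher simulation of independent loci with a Pool-Seq
# observation model. Generates the matched neutral null for cutoff
# calibration and powers the synthetic-data generator.

#' Simulate Wright-Fisher allele-frequency trajectories
#'
#' Independent loci, diploid population of effective size `ne` (2*ne gene
#' copies). Each generation, genic selection deterministically moves the
#' frequency to `p(1+s) / (1 + s*p)` and drift then draws the next-generation
#' count from `Binomial(2*ne, p_sel)`. Replicates share the starting
#' frequencies but drift independently.
#'
#' @param p0 numeric vector of starting frequencies (one per locus).
#' @param ne diploid effective population size (>= 2).
#' @param t number of generations (>= 1).
#' @param replicates number of replicate populations.
#' @param s selection coefficient, scalar or per-locus vector; 0 = neutral;
#'   must be > -1.
#' @param seed optional integer seed (fixed seed gives bit-identical output).
#' @param keep `"all"` returns every generation, `"ends"` only generations 0
#'   and t (memory-friendly for large cohorts).
#' @return numeric array `loci x generations_kept x replicates`; the
#'   generation dimension is named by generation number. Frequencies 0 and 1
#'   are absorbing.
#' @export
simulate_trajectories <- function(p0, ne, t, replicates = 1, s = 0,
                                  seed = NULL, keep = c("all", "ends")) {
  keep <- match.arg(keep)
  stopifnot(ne >= 2, t >= 1, replicates >= 1,
            all(p0 >= 0 & p0 <= 1), all(s > -1))
  .maybe_seed(seed)
  n <- length(p0)
  s <- rep_len(s, n)
  gens <- if (keep == "all") 0:t else c(0L, t)
  traj <- array(NA_real_, dim = c(n, length(gens), replicates),
                dimnames = list(NULL, paste0("gen", gens), NULL))
  two_ne <- 2 * ne
  for (k in seq_len(replicates)) {
    p <- p0
    traj[, 1, k] <- p
    for (g in seq_len(t)) {
      p_sel <- p * (1 + s) / (1 + s * p)
      p <- stats::rbinom(n, two_ne, p_sel) / two_ne
      if (keep == "all") traj[, g + 1, k] <- p
    }
    if (keep == "ends") traj[, 2, k] <- p
  }
  traj
}

# normalize a coverage model specification:
#   number                      -> Poisson with that mean
#   list(type="poisson", mean=) -> Poisson
#   list(type="empirical", depths=) -> resample the given depths
.coverage_model <- function(cm) {
  if (is.numeric(cm) && length(cm) == 1) cm <- list(type = "poisson", mean = cm)
  stopifnot(is.list(cm), cm$type %in% c("poisson", "empirical"))
  if (cm$type == "empirical") {
    if (length(cm$depths) == 0) .stopf("empirical depth pool is empty")
    stopifnot(all(cm$depths >= 1))
  } else {
    stopifnot(cm$mean > 0)
  }
  cm
}

.draw_depths <- function(cm, n) {
  cm <- .coverage_model(cm)
  if (cm$type == "empirical") {
    # sample.int avoids the sample() scalar pitfall for length-1 pools
    cm$depths[sample.int(length(cm$depths), n, replace = TRUE)]
  } else {
    d <- stats::rpois(n, cm$mean)
    # depths are conditioned positive: a sequenced library has >= 1 read
    while (any(d == 0)) d[d == 0] <- stats::rpois(sum(d == 0), cm$mean)
    d
  }
}

#' Observe true frequencies through the Pool-Seq two-stage sampling model
#'
#' For each locus and replicate: `S` chromosomes are pooled
#' (`Binomial(S, p)/S`), a read depth `R` is drawn from the coverage model,
#' and the focal-allele read count is `Binomial(R, p_pool)`. The resulting
#' read frequency has sampling variance `p(1-p) (1/S + 1/R - 1/(S R))`.
#'
#' @param p numeric matrix `loci x replicates` of true frequencies (a single
#'   time-point slice of a trajectory array, or a vector for one replicate).
#' @param pool_size chromosomes pooled per sample.
#' @param coverage coverage model: a Poisson mean, or
#'   `list(type = "poisson", mean = )`, or
#'   `list(type = "empirical", depths = )` to resample observed depths.
#' @param seed optional integer seed.
#' @return list with integer matrices `reads` (focal-allele read counts) and
#'   `depth`, both `loci x replicates`.
#' @export
observe_poolseq <- function(p, pool_size, coverage, seed = NULL) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 1)
  stopifnot(all(p >= 0 & p <= 1), pool_size >= 2)
  .maybe_seed(seed)
  n <- length(p)
  depth <- .draw_depths(coverage, n)
  p_pool <- stats::rbinom(n, pool_size, p) / pool_size
  reads <- stats::rbinom(n, depth, p_pool)
  list(reads = matrix(reads, nrow = nrow(p), dimnames = dimnames(p)),
       depth = matrix(depth, nrow = nrow(p), dimnames = dimnames(p)))
}

#' Simulate a matched neutral cohort for cutoff calibration
#'
#' Draws starting frequencies with replacement from observed founder
#' frequencies, evolves them neutrally (`s = 0`) for `t` generations in `K`
#' replicates at effective size `ne`, and observes both the founder and the
#' evolved time point through the Pool-Seq model, with depths drawn per time
#' point from the supplied coverage models. The founder is observed too: the
#' experimental contrast is between two sequenced samples.
#'
#' @param founder_freq numeric vector of observed founder allele frequencies
#'   to resample (the empirical spectrum), or a function `n -> frequencies`.
#' @param n_loci cohort size.
#' @param ne diploid effective size used for drift.
#' @param t generations.
#' @param replicates number of replicates K.
#' @param coverage_founder,coverage_evolved coverage models per time point
#'   (see [observe_poolseq()]); pass `list(type = "empirical", depths = )`
#'   to resample observed depths.
#' @param pool_sizes length-2: chromosomes pooled at founder and evolved
#'   time points.
#' @param seed optional integer seed.
#' @return list of `loci x K` matrices `a` (founder focal reads), `b`
#'   (founder other reads), `c` (evolved focal reads), `d` (evolved other
#'   reads), plus `p0` (true starting frequencies) and `p_final` (true final
#'   frequencies). Ready for [cmh_test_bulk()] and the Ne machinery.
#' @export
neutral_cohort <- function(founder_freq, n_loci, ne, t, replicates,
                           coverage_founder, coverage_evolved, pool_sizes,
                           seed = NULL) {
  stopifnot(n_loci >= 1, length(pool_sizes) == 2)
  .maybe_seed(seed)
  p0 <- if (is.function(founder_freq)) founder_freq(n_loci)
        else sample(founder_freq, n_loci, replace = TRUE)
  stopifnot(all(p0 >= 0 & p0 <= 1))
  traj <- simulate_trajectories(p0, ne, t, replicates, s = 0, keep = "ends")
  K <- replicates
  a <- b <- cc <- d <- matrix(0L, n_loci, K)
  for (k in seq_len(K)) {
    o0 <- observe_poolseq(traj[, 1, k], pool_sizes[1], coverage_founder)
    ot <- observe_poolseq(traj[, 2, k], pool_sizes[2], coverage_evolved)
    a[, k] <- o0$reads; b[, k] <- o0$depth - o0$reads
    cc[, k] <- ot$reads; d[, k] <- ot$depth - ot$reads
  }
  list(a = a, b = b, c = cc, d = d, p0 = p0,
       p_final = matrix(traj[, 2, ], nrow = n_loci))
}

#' Rare-variant-skewed founder spectrum sampler
#'
#' Beta(alpha, beta) frequencies conditioned on polymorphism in a census of
#' `census` diploids, i.e. truncated to
#' `(1/(2*census), 1 - 1/(2*census))` by rejection. With the default
#' Beta(0.2, 0.2) the spectrum is strongly skewed toward rare variants.
#'
#' @param n number of frequencies to draw.
#' @param alpha,beta Beta shape parameters (default 0.2, 0.2).
#' @param census census size in diploids defining the polymorphism bounds.
#' @return numeric vector of length `n`.
#' @export
founder_spectrum_beta <- function(n, alpha = 0.2, beta = 0.2, census = 1000) {
  stopifnot(alpha > 0, beta > 0, census >= 1)
  lo <- 1 / (2 * census); hi <- 1 - lo
  p <- stats::rbeta(n, alpha, beta)
  bad <- p <= lo | p >= hi
  while (any(bad)) {
    p[bad] <- stats::rbeta(sum(bad), alpha, beta)
    bad <- p <= lo | p >= hi
  }
  p
}
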