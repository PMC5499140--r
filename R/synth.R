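# Synthetic E&R data generator
#
# Stands in for an experiment's raw data: founder and evolved sync files with
# a known neutral background, optionally planted selected loci, and linked
# blocks whose trajectories are correlated with the selected focal locus.
# Linkage is emulated by trajectory mixing (a rho-weighted blend of the focal
# selected trajectory and the neighbor's own neutral trajectory), not by
# explicit recombination; this is a desk-scale device that produces testable
# peak structures.

#' Specification for the synthetic-data generator
#'
#' Defaults emulate the study conditions of a hot-adapted *D. simulans* E&R
#' experiment: 3 replicates, 60 nonoverlapping generations, census 1000
#' diploids, founder coverage ~259x and evolved ~100x, whole-population
#' pools (2000 chromosomes), and a rare-variant-skewed founder spectrum
#' (Beta(0.2, 0.2) conditioned polymorphic).
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param n_snps SNPs per chromosome (recycled over chromosomes).
#' @param spectrum list with `alpha`, `beta`: Beta parameters of the founder
#'   spectrum (truncated to the polymorphic range of the census).
#' @param replicates,generations,ne,census experimental parameters; `ne` is
#'   the drift effective size, `census` the diploid census.
#' @param coverage_founder,coverage_evolved coverage models (Poisson means by
#'   default; see [observe_poolseq()]).
#' @param pool_sizes chromosomes pooled at the two time points.
#' @param planted optional data.frame of selected loci: columns `chrom`,
#'   `pos`, `s`, and optionally `p0` (starting frequency; `NA` = drawn from
#'   the spectrum), `halfwidth` (linked-block half-width in bp, default 0) and
#'   `rho` (within-block trajectory correlation weight in `[0, 1]`, default 0).
#' @param seed integer seed; the generator is fully deterministic under it.
#' @return list of class `"synth_spec"`.
#' @export
synth_spec <- function(chromosomes = c(`2L` = 10e6, `2R` = 10e6),
                       n_snps = 10000,
                       spectrum = list(alpha = 0.2, beta = 0.2),
                       replicates = 3, generations = 60, ne = 285,
                       census = 1000,
                       coverage_founder = 259, coverage_evolved = 100,
                       pool_sizes = c(2000, 2000),
                       planted = NULL, seed = 1) {
  if (is.list(chromosomes)) chromosomes <- unlist(chromosomes)  # yaml configs
  if (is.list(pool_sizes)) pool_sizes <- unlist(pool_sizes)
  if (is.data.frame(planted) && nrow(planted) == 0) planted <- NULL
  stopifnot(!is.null(names(chromosomes)), all(chromosomes >= 1),
            all(n_snps >= 1), replicates >= 1, generations >= 1, ne >= 2,
            census >= 1, length(pool_sizes) == 2)
  n_snps <- rep_len(n_snps, length(chromosomes))
  if (!is.null(planted) && nrow(planted) > 0) {
    stopifnot(all(c("chrom", "pos", "s") %in% names(planted)))
    if (is.null(planted$p0)) planted$p0 <- NA_real_
    if (is.null(planted$halfwidth)) planted$halfwidth <- 0
    if (is.null(planted$rho)) planted$rho <- 0
    stopifnot(all(planted$chrom %in% names(chromosomes)),
              all(planted$rho >= 0 & planted$rho <= 1),
              all(planted$s > -1))
    if (any(planted$pos < 1 | planted$pos > chromosomes[planted$chrom])) {
      .stopf("planted locus outside chromosome bounds")
    }
  }
  structure(list(chromosomes = chromosomes, n_snps = n_snps,
                 spectrum = spectrum, replicates = replicates,
                 generations = generations, ne = ne, census = census,
                 coverage_founder = coverage_founder,
                 coverage_evolved = coverage_evolved,
                 pool_sizes = pool_sizes, planted = planted, seed = seed),
            class = "synth_spec")
}

#' Generate a synthetic E&R data set
#'
#' Background SNPs evolve neutrally and independently; planted loci evolve
#' under genic selection; block neighbors of a planted locus get, per
#' replicate, a final true frequency that is a rho-weighted mix of the focal
#' selected final frequency and their own independent neutral final
#' frequency, clipped to `[0, 1]` (with `rho = 0` every site is exchangeable
#' with the independent-loci simulator). All sites are then observed through
#' the Pool-Seq model at both time points.
#'
#' @param spec a [synth_spec()].
#' @param dir optional output directory; when given, writes
#'   `founder.sync`, `evolved.sync`, `truth.tsv` (per-locus p0, s and true
#'   final frequencies) and `planted_blocks.bed` (0-based half-open) and
#'   returns the paths alongside the objects.
#' @return list with `founder` and `evolved` (`sync` objects, sample labels
#'   `F1..FK` / `E1..EK`), `truth` (data.frame), `blocks` (data.frame of
#'   planted blocks, 1-based inclusive), and `paths` (when `dir` is given).
#' @export
generate_synth <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  K <- spec$replicates
  chroms <- rep(names(spec$chromosomes), spec$n_snps)
  pos <- unlist(lapply(seq_along(spec$chromosomes), function(i) {
    sort(sample.int(spec$chromosomes[[i]], spec$n_snps[i]))
  }), use.names = FALSE)
  n <- length(pos)
  s <- rep(0, n)
  p0 <- founder_spectrum_beta(n, spec$spectrum$alpha, spec$spectrum$beta,
                              spec$census)
  planted_idx <- integer(0)
  if (!is.null(spec$planted) && nrow(spec$planted) > 0) {
    pl <- spec$planted
    for (i in seq_len(nrow(pl))) {
      j <- which(chroms == pl$chrom[i] & pos == pl$pos[i])
      if (length(j) == 0) {  # insert the planted position
        at <- which(chroms == pl$chrom[i] & pos > pl$pos[i])[1]
        at <- if (is.na(at)) max(which(chroms == pl$chrom[i])) + 1L else at
        chroms <- append(chroms, pl$chrom[i], after = at - 1L)
        pos <- append(pos, pl$pos[i], after = at - 1L)
        p0 <- append(p0, founder_spectrum_beta(1, spec$spectrum$alpha,
                                               spec$spectrum$beta,
                                               spec$census), after = at - 1L)
        s <- append(s, 0, after = at - 1L)
        j <- at
      }
      s[j] <- pl$s[i]
      if (!is.na(pl$p0[i])) p0[j] <- pl$p0[i]
      planted_idx <- c(planted_idx, j)
    }
    n <- length(pos)
  }
  traj <- simulate_trajectories(p0, spec$ne, spec$generations, K, s = s,
                                keep = "ends")
  p_final <- matrix(traj[, 2, ], nrow = n)
  # linked blocks: mix neighbor final frequencies toward the focal trajectory
  blocks <- NULL
  if (length(planted_idx) > 0) {
    pl <- spec$planted
    blocks <- data.frame(chrom = pl$chrom,
                         start = pmax(1, pl$pos - pl$halfwidth),
                         end = pmin(spec$chromosomes[pl$chrom],
                                    pl$pos + pl$halfwidth),
                         pos = pl$pos, s = pl$s, rho = pl$rho,
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(pl))) {
      if (pl$rho[i] <= 0 || pl$halfwidth[i] <= 0) next
      nb <- which(chroms == pl$chrom[i] &
                    abs(pos - pl$pos[i]) <= pl$halfwidth[i])
      nb <- setdiff(nb, planted_idx)
      if (length(nb) == 0) next
      focal <- p_final[planted_idx[i], ]
      mixed <- pl$rho[i] * matrix(focal, length(nb), K, byrow = TRUE) +
        (1 - pl$rho[i]) * p_final[nb, , drop = FALSE]
      p_final[nb, ] <- pmin(pmax(mixed, 0), 1)
    }
  }
  # observation at both time points
  f_reads <- f_depth <- e_reads <- e_depth <- matrix(0L, n, K)
  for (k in seq_len(K)) {
    o0 <- observe_poolseq(p0, spec$pool_sizes[1], spec$coverage_founder)
    ot <- observe_poolseq(p_final[, k], spec$pool_sizes[2],
                          spec$coverage_evolved)
    f_reads[, k] <- o0$reads; f_depth[, k] <- o0$depth
    e_reads[, k] <- ot$reads; e_depth[, k] <- ot$depth
  }
  # assign two nucleotides per site: focal allele and alternative
  al <- matrix(.NUC_ORDER[t(apply(matrix(stats::runif(n * 4), n), 1,
                                  order))[, 1:2]], n)
  counts_array <- function(reads, depth) {
    cnt <- array(0L, dim = c(n, K, 6))
    for (k in seq_len(K)) {
      for (b in 1:4) {
        sel <- al[, 1] == .SYNC_ALLELES[b]
        cnt[sel, k, b] <- cnt[sel, k, b] + reads[sel, k]
        sel2 <- al[, 2] == .SYNC_ALLELES[b]
        cnt[sel2, k, b] <- cnt[sel2, k, b] + (depth[sel2, k] - reads[sel2, k])
      }
    }
    cnt
  }
  founder <- new_sync(chroms, pos, al[, 1], counts_array(f_reads, f_depth),
                      paste0("F", seq_len(K)))
  evolved <- new_sync(chroms, pos, al[, 1], counts_array(e_reads, e_depth),
                      paste0("E", seq_len(K)))
  truth <- data.frame(chrom = chroms, pos = pos, allele = al[, 1],
                      p0 = p0, s = s, stringsAsFactors = FALSE)
  for (k in seq_len(K)) truth[[paste0("p_final_", k)]] <- p_final[, k]
  out <- list(founder = founder, evolved = evolved, truth = truth,
              blocks = blocks)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(founder = file.path(dir, "founder.sync"),
                  evolved = file.path(dir, "evolved.sync"),
                  truth = file.path(dir, "truth.tsv"),
                  blocks = file.path(dir, "planted_blocks.bed"))
    write_sync(founder, paths$founder)
    write_sync(evolved, paths$evolved)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    bed <- if (is.null(blocks)) data.frame() else
      data.frame(blocks$chrom, blocks$start - 1L, blocks$end)
    utils::write.table(bed, paths$blocks, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    out$paths <- paths
  }
  out
}
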