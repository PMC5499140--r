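# fixtures built in code: random sync objects, polarized toys, random
# replicated 2x2 tables

make_random_sync <- function(n = 50, n_samples = 4, seed = 1,
                             chroms = c("2L", "2R")) {
  set.seed(seed)
  chrom <- sort(sample(chroms, n, replace = TRUE))
  pos <- unlist(lapply(unique(chrom), function(ch) {
    sort(sample.int(1e6, sum(chrom == ch)))
  }), use.names = FALSE)
  counts <- array(0L, dim = c(n, n_samples, 6))
  # two main alleles per site plus occasional third-allele / N / del reads
  for (i in seq_len(n)) {
    alleles <- sample(1:4, 2)
    p <- runif(1, 0.05, 0.95)
    for (j in seq_len(n_samples)) {
      depth <- rpois(1, 80) + 1
      a1 <- rbinom(1, depth, p)
      counts[i, j, alleles[1]] <- a1
      counts[i, j, alleles[2]] <- depth - a1
      counts[i, j, sample(c(setdiff(1:4, alleles), 5, 6), 1)] <-
        rbinom(1, 3, 0.3)
    }
  }
  new_sync(chrom, pos, c("A", "T", "C", "G")[sample(1:4, n, replace = TRUE)],
           counts, paste0("s", seq_len(n_samples)))
}

# biallelic toy from explicit major/minor count matrices
make_biallelic <- function(major_counts, minor_counts,
                           founder = colnames(major_counts),
                           chrom = NULL, pos = NULL, dropped = NULL) {
  n <- nrow(major_counts)
  labels <- colnames(major_counts)
  sync_counts <- array(0L, dim = c(n, ncol(major_counts), 6))
  sync_counts[, , 1] <- major_counts  # A
  sync_counts[, , 2] <- minor_counts  # T
  if (!is.null(dropped)) sync_counts[, , 3] <- dropped  # C
  s <- new_sync(chrom %||% rep("2L", n), pos %||% seq(10, by = 10, length.out = n),
                rep("A", n), sync_counts, labels)
  polarize(s, founder)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random replicated 2x2 tables with all-positive cells (no degenerate margins)
random_tables <- function(n_tables, K, seed, max_count = 60) {
  set.seed(seed)
  lapply(seq_len(n_tables), function(i) {
    list(a = sample(1:max_count, K, TRUE), b = sample(1:max_count, K, TRUE),
         c = sample(1:max_count, K, TRUE), d = sample(1:max_count, K, TRUE))
  })
}

# reference CMH via stats::mantelhaen.test on a 2x2xK array; for a single
# stratum (mantelhaen.test needs K >= 2) via stats::chisq.test and the exact
# identity MH = Pearson * (T - 1) / T, which holds with and without the
# continuity correction
mantelhaen_ref <- function(tab, correction) {
  K <- length(tab$a)
  if (K == 1) {
    m <- matrix(c(tab$a, tab$b, tab$c, tab$d), 2, 2, byrow = TRUE)
    Tk <- sum(m)
    stat <- unname(suppressWarnings(
      stats::chisq.test(m, correct = correction)$statistic)) * (Tk - 1) / Tk
    return(list(statistic = stat,
                p_value = stats::pchisq(stat, 1, lower.tail = FALSE)))
  }
  arr <- array(0, dim = c(2, 2, K))
  arr[1, 1, ] <- tab$a; arr[1, 2, ] <- tab$b
  arr[2, 1, ] <- tab$c; arr[2, 2, ] <- tab$d
  # rows = time point, cols = allele; stratum = replicate
  res <- stats::mantelhaen.test(arr, correct = correction, exact = FALSE)
  list(statistic = unname(res$statistic), p_value = res$p.value)
}
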