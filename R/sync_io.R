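# sync file I/O and polarization
#
# The sync format (PoPoolation2) is tab-separated:
#   chrom  pos  ref  A:T:C:G:N:del  [A:T:C:G:N:del ...]
# one column of colon-separated counts per population sample.

.SYNC_ALLELES <- c("A", "T", "C", "G", "N", "del")
# fixed nucleotide order used for polarization tie-breaks
.NUC_ORDER <- c("A", "C", "G", "T")

#' Construct a sync object
#'
#' Container for per-site, per-sample nucleotide read counts as parsed from a
#' sync file: one count sextuple (A, T, C, G, N, deletion) per sample.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions (`pos >= 1`).
#' @param ref character vector of reference bases (A/C/G/T/N).
#' @param counts integer array `sites x samples x 6`, allele order
#'   A, T, C, G, N, del; all entries non-negative.
#' @param sample_labels character vector naming the sample columns, e.g.
#'   `c("F1", "F2", "F3", "E1", "E2", "E3")` for founder and evolved
#'   replicates.
#' @return an object of class `"sync"`.
#' @export
new_sync <- function(chrom, pos, ref, counts, sample_labels) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n)
  if (n == 0 && is.null(counts)) {
    counts <- array(integer(0), dim = c(0, length(sample_labels), 6))
  }
  stopifnot(length(dim(counts)) == 3, dim(counts)[1] == n, dim(counts)[3] == 6)
  if (dim(counts)[2] != length(sample_labels)) {
    .stopf("counts has %d sample columns but %d sample_labels given",
           dim(counts)[2], length(sample_labels))
  }
  if (n > 0) {
    if (any(pos < 1)) .stopf("positions must be >= 1")
    if (any(counts < 0)) .stopf("allele counts must be non-negative")
    if (any(counts != round(counts))) .stopf("allele counts must be integers")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(NULL, sample_labels, .SYNC_ALLELES)
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), counts = counts,
         sample_labels = as.character(sample_labels)),
    class = "sync")
}

#' @export
print.sync <- function(x, ...) {
  cat(sprintf("sync: %d sites, %d samples (%s)\n", length(x$pos),
              length(x$sample_labels), paste(x$sample_labels, collapse = ", ")))
  invisible(x)
}

#' Number of sites in a sync or biallelic object
#' @param x a `sync` or `biallelic` object.
#' @return integer count of sites.
#' @export
n_sites <- function(x) length(x$pos)

#' Per-sample read coverage
#'
#' Coverage is the number of A/T/C/G reads; N and deletion counts are
#' excluded by convention (allele frequencies are ratios of nucleotide
#' reads).
#'
#' @param x a `sync` object.
#' @return integer matrix `sites x samples`.
#' @export
sync_coverage <- function(x) {
  stopifnot(inherits(x, "sync"))
  cov <- x$counts[, , "A", drop = FALSE] + x$counts[, , "T", drop = FALSE] +
    x$counts[, , "C", drop = FALSE] + x$counts[, , "G", drop = FALSE]
  matrix(cov, nrow = dim(x$counts)[1], ncol = dim(x$counts)[2],
         dimnames = list(NULL, x$sample_labels))
}

#' Read a sync file
#'
#' Parses a PoPoolation2-style synchronized allele-count file. Every line must
#' have the same number of columns; count fields must be six colon-separated
#' non-negative integers. Malformed lines raise an error naming the line
#' number.
#'
#' @param path file path.
#' @param sample_labels optional labels for the sample columns; defaults to
#'   `s1, s2, ...`.
#' @return a [new_sync()] object; sites in file order.
#' @export
read_sync <- function(path, sample_labels = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(new_sync(character(0), integer(0), character(0), NULL,
                    sample_labels %||% character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1])) {
    .stopf("inconsistent column count at line %d (%d fields, expected %d)",
           which(nf != nf[1])[1], nf[which(nf != nf[1])[1]], nf[1])
  }
  if (nf[1] < 4) .stopf("sync lines need >= 4 tab-separated fields, got %d", nf[1])
  n <- length(lines)
  n_samp <- nf[1] - 3
  m <- matrix(unlist(fields), nrow = n, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) .stopf("non-integer position at line %d", which(is.na(pos))[1])
  if (any(pos < 1)) .stopf("position < 1 at line %d", which(pos < 1)[1])
  counts <- array(0L, dim = c(n, n_samp, 6))
  for (j in seq_len(n_samp)) {
    sp <- strsplit(m[, 3 + j], ":", fixed = TRUE)
    bad <- lengths(sp) != 6
    if (any(bad)) {
      .stopf("count field with %d values (expected 6) at line %d, sample %d",
             lengths(sp)[which(bad)[1]], which(bad)[1], j)
    }
    v <- suppressWarnings(as.integer(unlist(sp)))
    if (anyNA(v)) {
      .stopf("non-integer allele count at line %d, sample %d",
             ceiling(which(is.na(v))[1] / 6), j)
    }
    if (any(v < 0)) .stopf("negative allele count at line %d, sample %d",
                           ceiling(which(v < 0)[1] / 6), j)
    counts[, j, ] <- matrix(v, nrow = n, byrow = TRUE)
  }
  if (is.null(sample_labels)) sample_labels <- paste0("s", seq_len(n_samp))
  if (length(sample_labels) != n_samp) {
    .stopf("file has %d sample columns but %d sample_labels given",
           n_samp, length(sample_labels))
  }
  new_sync(m[, 1], pos, m[, 3], counts, sample_labels)
}

#' Write a sync file
#'
#' Inverse of [read_sync()]: `write_sync(read_sync(f), g)` reproduces `f`
#' byte-identically for canonical input.
#'
#' @param x a `sync` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(x, path) {
  stopifnot(inherits(x, "sync"))
  n <- n_sites(x)
  if (n == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  samp_cols <- vapply(seq_along(x$sample_labels), function(j) {
    do.call(paste, c(lapply(1:6, function(k) x$counts[, j, k]), sep = ":"))
  }, character(n))
  samp_cols <- matrix(samp_cols, nrow = n)
  lines <- do.call(paste, c(list(x$chrom, x$pos, x$ref),
                            lapply(seq_len(ncol(samp_cols)),
                                   function(j) samp_cols[, j]),
                            sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Combine the samples of two sync objects over the same sites
#'
#' Column-binds the sample columns (e.g. founder and evolved files listing
#' identical sites).
#'
#' @param x,y `sync` objects with identical chrom/pos/ref.
#' @return a `sync` object with the samples of `x` followed by those of `y`.
#' @export
combine_sync <- function(x, y) {
  stopifnot(inherits(x, "sync"), inherits(y, "sync"))
  if (n_sites(x) != n_sites(y) || !all(x$chrom == y$chrom & x$pos == y$pos)) {
    .stopf("sync objects must list the same sites in the same order")
  }
  n <- n_sites(x)
  S1 <- length(x$sample_labels); S2 <- length(y$sample_labels)
  counts <- array(0L, dim = c(n, S1 + S2, 6))
  counts[, seq_len(S1), ] <- x$counts
  counts[, S1 + seq_len(S2), ] <- y$counts
  new_sync(x$chrom, x$pos, x$ref, counts,
           c(x$sample_labels, y$sample_labels))
}

#' Polarize sites to a major/minor allele axis
#'
#' Determines, once per site, the major and minor allele from the founder
#' samples pooled together: major = highest summed A/C/G/T count, minor =
#' second highest, ties broken by the fixed nucleotide order A < C < G < T.
#' The same axis is then used for every sample of the site, so founder and
#' evolved frequencies are directly comparable. Reads of third/fourth alleles
#' (and N/deletions) are dropped from the biallelic counts but retained in the
#' `dropped` matrix, so per-sample `major + minor + dropped` equals the
#' original total reads.
#'
#' @param x a `sync` object.
#' @param founder_samples character vector of founder sample labels (subset of
#'   `x$sample_labels`).
#' @param on_zero what to do with sites whose pooled founder A/C/G/T coverage
#'   is zero (polarization undefined): `"error"` (default) or `"drop"`.
#' @return an object of class `"biallelic"`: a list with `chrom`, `pos`,
#'   `major`, `minor` (nucleotides), matrices `major_counts`, `minor_counts`,
#'   `dropped` (`sites x samples`, dropped = N + del + other alleles), and the
#'   sample bookkeeping.
#' @export
polarize <- function(x, founder_samples, on_zero = c("error", "drop")) {
  stopifnot(inherits(x, "sync"), length(founder_samples) >= 1)
  on_zero <- match.arg(on_zero)
  fidx <- match(founder_samples, x$sample_labels)
  if (anyNA(fidx)) {
    .stopf("unknown founder sample label(s): %s",
           paste(founder_samples[is.na(fidx)], collapse = ", "))
  }
  n <- n_sites(x)
  if (n == 0) {
    return(.new_biallelic(character(0), integer(0), character(0), character(0),
                          e <- matrix(0L, 0, length(x$sample_labels)), e, e,
                          x$sample_labels, founder_samples))
  }
  # pooled founder counts, columns in tie-break order A,C,G,T
  pooled <- sapply(.NUC_ORDER, function(al) {
    rowSums(matrix(x$counts[, fidx, al], nrow = n))
  })
  pooled <- matrix(pooled, nrow = n, dimnames = list(NULL, .NUC_ORDER))
  zero <- rowSums(pooled) == 0
  if (any(zero)) {
    if (on_zero == "error") {
      .stopf("polarization undefined: zero founder A/C/G/T coverage at %s:%d",
             x$chrom[which(zero)[1]], x$pos[which(zero)[1]])
    }
    keep <- which(!zero)
    x <- .subset_sync(x, keep)
    pooled <- pooled[keep, , drop = FALSE]
    n <- n_sites(x)
  }
  maj_i <- max.col(pooled, ties.method = "first")
  pooled2 <- pooled
  pooled2[cbind(seq_len(n), maj_i)] <- -1L
  min_i <- max.col(pooled2, ties.method = "first")
  major <- .NUC_ORDER[maj_i]
  minor <- .NUC_ORDER[min_i]
  S <- length(x$sample_labels)
  flat <- matrix(x$counts, nrow = n)  # n x (S*6), allele-major blocks
  major_counts <- minor_counts <- total <- matrix(0L, n, S)
  for (j in seq_len(S)) {
    maj_col <- (match(major, .SYNC_ALLELES) - 1L) * S + j
    min_col <- (match(minor, .SYNC_ALLELES) - 1L) * S + j
    major_counts[, j] <- flat[cbind(seq_len(n), maj_col)]
    minor_counts[, j] <- flat[cbind(seq_len(n), min_col)]
    total[, j] <- rowSums(matrix(x$counts[, j, ], nrow = n))
  }
  dropped <- total - major_counts - minor_counts
  .new_biallelic(x$chrom, x$pos, major, minor, major_counts, minor_counts,
                 dropped, x$sample_labels, founder_samples)
}

.new_biallelic <- function(chrom, pos, major, minor, major_counts,
                           minor_counts, dropped, sample_labels,
                           founder_samples) {
  lab <- function(m) {
    dimnames(m) <- list(NULL, sample_labels)
    m
  }
  structure(
    list(chrom = chrom, pos = as.integer(pos), major = major, minor = minor,
         major_counts = lab(major_counts), minor_counts = lab(minor_counts),
         dropped = lab(dropped), sample_labels = sample_labels,
         founder_samples = founder_samples),
    class = "biallelic")
}

#' @export
print.biallelic <- function(x, ...) {
  cat(sprintf("biallelic: %d sites, %d samples (founders: %s)\n",
              n_sites(x), length(x$sample_labels),
              paste(x$founder_samples, collapse = ", ")))
  invisible(x)
}

#' Subset sites of a biallelic object
#' @param x a `biallelic` object.
#' @param i site index (integer or logical).
#' @param ... unused.
#' @export
`[.biallelic` <- function(x, i, ...) {
  .new_biallelic(x$chrom[i], x$pos[i], x$major[i], x$minor[i],
                 x$major_counts[i, , drop = FALSE],
                 x$minor_counts[i, , drop = FALSE],
                 x$dropped[i, , drop = FALSE],
                 x$sample_labels, x$founder_samples)
}

#' @export
as.data.frame.biallelic <- function(x, ...) {
  data.frame(chrom = x$chrom, pos = x$pos, major = x$major, minor = x$minor,
             stringsAsFactors = FALSE)
}

#' Per-sample A/C/G/T coverage of polarized sites
#' @param x a `biallelic` object.
#' @return integer matrix `sites x samples` of total reads
#'   (major + minor + dropped).
#' @export
biallelic_coverage <- function(x) {
  stopifnot(inherits(x, "biallelic"))
  x$major_counts + x$minor_counts + x$dropped
}

#' Major-allele read frequencies
#' @param x a `biallelic` object.
#' @param samples optional sample labels to restrict columns.
#' @return numeric matrix of major-allele frequencies, `NaN` where
#'   major + minor coverage is zero.
#' @export
major_freq <- function(x, samples = NULL) {
  stopifnot(inherits(x, "biallelic"))
  j <- if (is.null(samples)) seq_along(x$sample_labels)
       else match(samples, x$sample_labels)
  if (anyNA(j)) .stopf("unknown sample label(s)")
  maj <- x$major_counts[, j, drop = FALSE]
  tot <- maj + x$minor_counts[, j, drop = FALSE]
  maj / tot
}

.subset_sync <- function(x, i) {
  new_sync(x$chrom[i], x$pos[i], x$ref[i],
           x$counts[i, , , drop = FALSE], x$sample_labels)
}
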