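# Sliding-window averaging of candidate scores and region merging
#
# Candidate SNP -log10 p values are averaged in 200-kb windows sliding every
# 100 kb; windows whose average exceeds the CMH cutoff are merged into
# selected regions. Averaging is done on the -log10 scale: window averages
# are compared against cutoffs like 31, which is only coherent for
# -log10-transformed p values.

#' Sliding-window average candidate scores
#'
#' Windows tile each chromosome from position 1, advancing by `step`; the
#' final window is truncated at the chromosome end (and still scored).
#' Coordinates are 1-based inclusive.
#'
#' @param candidates data.frame with `chrom`, `pos`, `neg_log10_p` (as from
#'   [call_candidates()]).
#' @param chrom_lengths named numeric vector of chromosome lengths; must
#'   cover every chromosome with candidates.
#' @param window window length in bp (default 200000).
#' @param step window offset in bp (default 100000).
#' @return data.frame: chrom, start, end, n_candidates, mean_score
#'   (`NA` when the window holds no candidates).
#' @export
window_scores <- function(candidates, chrom_lengths, window = 200000,
                          step = 100000) {
  stopifnot(window >= 1, step >= 1, !is.null(names(chrom_lengths)))
  miss <- setdiff(unique(candidates$chrom), names(chrom_lengths))
  if (length(miss)) .stopf("no chromosome length for: %s", paste(miss, collapse = ", "))
  out <- list()
  for (chr in names(chrom_lengths)) {
    len <- chrom_lengths[[chr]]
    ci <- candidates$chrom == chr
    if (any(candidates$pos[ci] > len)) {
      .stopf("candidate at %s:%d beyond chromosome length %d",
             chr, max(candidates$pos[ci]), len)
    }
    pos <- candidates$pos[ci]
    score <- candidates$neg_log10_p[ci]
    o <- order(pos); pos <- pos[o]; score <- score[o]
    cs <- cumsum(c(0, score))
    starts <- seq(1, len, by = step)
    ends <- pmin(starts + window - 1, len)
    # candidates in [start, end] located on the sorted positions
    lo <- findInterval(starts - 1, pos)   # count of pos <= start - 1
    hi <- findInterval(ends, pos)         # count of pos <= end
    ncand <- hi - lo
    msc <- ifelse(ncand > 0, (cs[hi + 1] - cs[lo + 1]) / ncand, NA_real_)
    out[[chr]] <- data.frame(chrom = chr, start = starts, end = ends,
                             n_candidates = ncand, mean_score = msc,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Merge qualifying windows into selected regions
#'
#' Windows with `mean_score > cutoff` (strict; windows without candidates
#' never qualify) that overlap or abut are unioned into regions.
#'
#' @param scores a [window_scores()] result.
#' @param cutoff the empirical CMH cutoff (numeric or a `cutoff_result`).
#' @param candidates optional candidate table used to count unique candidate
#'   SNPs per region.
#' @param chrom_lengths optional named lengths used for the genome-fraction
#'   summary.
#' @return data.frame of class `"selected_regions"`: chrom, start, end,
#'   n_windows, max_mean_score, n_candidates (`NA` if `candidates` not
#'   given). Attribute `"summary"` holds `n_regions`, `total_bp`, and
#'   `fraction_genome` (when lengths are supplied).
#' @export
merge_regions <- function(scores, cutoff, candidates = NULL,
                          chrom_lengths = NULL) {
  if (inherits(cutoff, "cutoff_result")) cutoff <- cutoff$cutoff
  qual <- scores[!is.na(scores$mean_score) & scores$mean_score > cutoff, ,
                 drop = FALSE]
  if (nrow(qual) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      max_mean_score = numeric(0), n_candidates = integer(0))
  } else {
    gr <- GenomicRanges::GRanges(qual$chrom,
                                 IRanges::IRanges(qual$start, qual$end))
    red <- GenomicRanges::reduce(gr)  # merges overlapping and abutting
    ov <- GenomicRanges::findOverlaps(gr, red)
    nwin <- tabulate(S4Vectors::subjectHits(ov), length(red))
    maxsc <- tapply(qual$mean_score[S4Vectors::queryHits(ov)],
                    S4Vectors::subjectHits(ov), max)
    ncand <- rep(NA_integer_, length(red))
    if (!is.null(candidates)) {
      cgr <- GenomicRanges::GRanges(candidates$chrom,
                                    IRanges::IRanges(candidates$pos,
                                                     candidates$pos))
      ncand <- GenomicRanges::countOverlaps(red, cgr)
    }
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                      start = GenomicRanges::start(red),
                      end = GenomicRanges::end(red),
                      n_windows = nwin,
                      max_mean_score = as.numeric(maxsc),
                      n_candidates = ncand,
                      stringsAsFactors = FALSE)
  }
  total_bp <- sum(out$end - out$start + 1)
  summ <- list(n_regions = nrow(out), total_bp = total_bp,
               fraction_genome = if (!is.null(chrom_lengths))
                 total_bp / sum(chrom_lengths) else NA_real_)
  attr(out, "summary") <- summ
  class(out) <- c("selected_regions", "data.frame")
  out
}

#' Write selected regions to a BED file
#'
#' Internal 1-based inclusive coordinates are converted to BED 0-based
#' half-open.
#'
#' @param regions a [merge_regions()] result.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(regions$chrom, regions$start - 1L, regions$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Allele-frequency-change summary of candidate SNPs
#'
#' Frequencies are averaged across replicates at the founder and final time
#' points and polarized by the rising allele (the allele whose replicate-
#' averaged change is positive). The fixation fraction is the proportion of
#' candidates whose final major-allele frequency (max of the rising-allele
#' frequency and its complement) reaches `fixation_threshold`.
#'
#' @param candidates a [cmh_scan()]/[call_candidates()] table with
#'   per-replicate frequency columns `f0_k` and `ft_k`.
#' @param fixation_threshold default 0.9.
#' @return list of class `"afc_summary"`: `table` (per-candidate start_freq,
#'   end_freq, change on the rising-allele axis, and `near_fixation` flag),
#'   `fixation_fraction`, `n`.
#' @export
afc_summary <- function(candidates, fixation_threshold = 0.9) {
  f0c <- grep("^f0_", names(candidates), value = TRUE)
  ftc <- grep("^ft_", names(candidates), value = TRUE)
  if (length(f0c) == 0 || length(ftc) == 0) {
    .stopf("candidate table lacks per-replicate frequency columns f0_*/ft_*")
  }
  f0 <- rowMeans(candidates[, f0c, drop = FALSE], na.rm = TRUE)
  ft <- rowMeans(candidates[, ftc, drop = FALSE], na.rm = TRUE)
  rising <- ft >= f0  # on the major-allele axis; flip where it fell
  start_freq <- ifelse(rising, f0, 1 - f0)
  end_freq <- ifelse(rising, ft, 1 - ft)
  near_fix <- pmax(end_freq, 1 - end_freq) >= fixation_threshold
  tab <- data.frame(chrom = candidates$chrom, pos = candidates$pos,
                    start_freq = start_freq, end_freq = end_freq,
                    change = end_freq - start_freq,
                    near_fixation = near_fix, stringsAsFactors = FALSE)
  structure(list(table = tab,
                 fixation_fraction = if (nrow(tab)) mean(near_fix) else NA_real_,
                 n = nrow(tab),
                 fixation_threshold = fixation_threshold),
            class = "afc_summary")
}

#' @export
print.afc_summary <- function(x, ...) {
  cat(sprintf("AFC summary of %d candidates: %.1f%% near fixation (threshold %.2f)\n",
              x$n, 100 * x$fixation_fraction, x$fixation_threshold))
  invisible(x)
}

#' @export
plot.afc_summary <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::hist(x$table$start_freq, breaks = 20, main = "Founder frequency",
                 xlab = "rising-allele frequency", ...)
  graphics::hist(x$table$end_freq, breaks = 20, main = "Final frequency",
                 xlab = "rising-allele frequency", ...)
  graphics::hist(x$table$change, breaks = 20, main = "Frequency change",
                 xlab = "change", ...)
  invisible(x)
}
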