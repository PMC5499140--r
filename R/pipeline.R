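# End-to-end orchestration: sync input (or synthetic generation) -> SNP
# filtering -> CMH scan -> windowed Ne estimation -> matched neutral
# simulation -> empirical cutoff -> candidate SNPs -> selected regions ->
# allele-frequency-change summaries. Stage products are plain sync/TSV/BED
# files so any stage can be re-run standalone.

.pipeline_defaults <- function() {
  list(
    founder_labels = NULL, evolved_labels = NULL,
    min_minor_count = 1, coverage_quantile = 0.01, mask = NULL,
    downsample_to = NULL,
    generations = 60, census = 1000, pool_sizes = c(2000, 2000),
    window_snps = 1000, plan = "I",
    fpr = 0.02, n_neutral = 1e5, continuity_correction = TRUE,
    window_bp = 200000, step_bp = 100000,
    fixation_threshold = 0.9,
    chrom_lengths = NULL, species = "synthetic", seed = 1)
}

#' Run the full selection-scan pipeline
#'
#' @param config a named list (or path to a YAML file) overriding the
#'   defaults. Either supply `founder_sync`/`evolved_sync` paths together
#'   with `founder_labels`/`evolved_labels`, or a `synth` entry (arguments
#'   for [synth_spec()]) to generate the input. Other entries:
#'   `min_minor_count`, `coverage_quantile`, `mask` (BED path),
#'   `downsample_to`, `generations`, `census`, `pool_sizes`, `window_snps`,
#'   `plan`, `fpr`, `n_neutral`, `continuity_correction`, `window_bp`,
#'   `step_bp`, `fixation_threshold`, `chrom_lengths` (named vector; default
#'   taken from the synthetic spec or the maximum observed position),
#'   `species` (free-text label), `seed`.
#' @param out_dir directory for stage artifacts (TSV/BED/JSON); created if
#'   missing.
#' @return report list (also written to `report.json`): candidate count,
#'   cutoff, Ne estimates, region count / bp / genome fraction, fixation
#'   fraction, and all filter/skip tallies.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  for (f in c("pool_sizes", "chrom_lengths")) {
    if (is.list(cfg[[f]])) cfg[[f]] <- unlist(cfg[[f]])  # yaml configs
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(cfg$seed)
  stage <- function(msg, ...) message(sprintf(paste0("[erscan] ", msg), ...))

  # --- input ------------------------------------------------------------
  if (!is.null(cfg$synth)) {
    stage("generating synthetic data")
    spec <- do.call(synth_spec, cfg$synth)
    syn <- generate_synth(spec, dir = file.path(out_dir, "synth"))
    founder <- syn$founder; evolved <- syn$evolved
    cfg$founder_labels <- founder$sample_labels
    cfg$evolved_labels <- evolved$sample_labels
    cfg$chrom_lengths <- cfg$chrom_lengths %||% spec$chromosomes
    cfg$generations <- spec$generations
    cfg$census <- spec$census
    cfg$pool_sizes <- spec$pool_sizes
  } else {
    stage("reading sync files")
    founder <- read_sync(cfg$founder_sync, cfg$founder_labels)
    evolved <- read_sync(cfg$evolved_sync, cfg$evolved_labels)
    cfg$founder_labels <- founder$sample_labels
    cfg$evolved_labels <- evolved$sample_labels
  }
  combined <- combine_sync(founder, evolved)

  # --- filtering --------------------------------------------------------
  stage("polarizing %d sites", n_sites(combined))
  bi <- polarize(combined, cfg$founder_labels, on_zero = "drop")
  snps <- call_snps(bi, cfg$min_minor_count)
  stage("SNP calling kept %d / %d sites", n_sites(snps), n_sites(bi))
  th <- coverage_thresholds(snps, cfg$coverage_quantile)
  filt <- apply_coverage_filter(snps, th)
  cov_removed <- attr(filt, "removed")
  stage("coverage filter removed %d sites", cov_removed)
  masked_removed <- 0L
  if (!is.null(cfg$mask)) {
    filt2 <- mask_intervals(filt, cfg$mask)
    masked_removed <- attr(filt2, "removed")
    filt <- filt2
    stage("mask removed %d sites", masked_removed)
  }
  if (!is.null(cfg$downsample_to)) {
    filt <- downsample_counts(filt, cfg$downsample_to)
    stage("downsampled to mean coverage %.0f", cfg$downsample_to)
  }

  # --- CMH scan ---------------------------------------------------------
  stage("CMH scan on %d SNPs", n_sites(filt))
  scan <- cmh_scan(filt, cfg$founder_labels, cfg$evolved_labels,
                   correction = cfg$continuity_correction)
  utils::write.table(scan, file.path(out_dir, "cmh.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- Ne ---------------------------------------------------------------
  stage("windowed Ne estimation")
  nw <- ne_scan(filt, cfg$founder_labels, cfg$evolved_labels,
                t = cfg$generations, pool_sizes = cfg$pool_sizes,
                census = cfg$census, window_snps = cfg$window_snps,
                plan = cfg$plan)
  agg <- aggregate_ne(nw)
  stage("aggregate Ne = %.1f", agg$ne)
  utils::write.table(nw, file.path(out_dir, "ne_windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- matched neutral null and cutoff ---------------------------------
  stage("simulating neutral cohort of %d loci at Ne = %.0f",
        cfg$n_neutral, agg$ne)
  f0 <- major_freq(filt, cfg$founder_labels)
  depths0 <- as.vector(filt$major_counts[, cfg$founder_labels] +
                         filt$minor_counts[, cfg$founder_labels])
  deptht <- as.vector(filt$major_counts[, cfg$evolved_labels] +
                        filt$minor_counts[, cfg$evolved_labels])
  cohort <- neutral_cohort(
    founder_freq = as.vector(f0)[!is.na(as.vector(f0))],
    n_loci = cfg$n_neutral, ne = max(2, round(agg$ne)),
    t = cfg$generations, replicates = length(cfg$founder_labels),
    coverage_founder = list(type = "empirical", depths = depths0[depths0 >= 1]),
    coverage_evolved = list(type = "empirical", depths = deptht[deptht >= 1]),
    pool_sizes = cfg$pool_sizes)
  null_cmh <- cmh_test_bulk(cohort$a, cohort$b, cohort$c, cohort$d,
                            correction = cfg$continuity_correction)
  cut <- empirical_cutoff(null_cmh$neg_log10_p, cfg$fpr)
  stage("empirical cutoff -log10 p > %.3f at FPR %g", cut$cutoff, cut$fpr)

  # --- candidates, regions, summaries ----------------------------------
  cand <- call_candidates(scan, cut)
  stage("%d candidate SNPs", nrow(cand))
  utils::write.table(cand, file.path(out_dir, "candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lens <- cfg$chrom_lengths
  if (is.null(lens)) {
    lens <- tapply(filt$pos, filt$chrom, max)
    lens <- stats::setNames(as.numeric(lens), names(lens))
  }
  ws <- window_scores(cand, lens, cfg$window_bp, cfg$step_bp)
  reg <- merge_regions(ws, cut, candidates = cand, chrom_lengths = lens)
  rsum <- attr(reg, "summary")
  stage("%d selected regions covering %.2f Mb (%.1f%% of genome)",
        rsum$n_regions, rsum$total_bp / 1e6, 100 * rsum$fraction_genome)
  utils::write.table(ws, file.path(out_dir, "window_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_regions_bed(reg, file.path(out_dir, "regions.bed"))
  afc <- if (nrow(cand)) afc_summary(cand, cfg$fixation_threshold) else NULL

  report <- list(
    species = cfg$species, seed = cfg$seed,
    n_sites_input = n_sites(combined),
    n_snps_called = n_sites(snps),
    n_removed_coverage = cov_removed,
    n_removed_mask = masked_removed,
    n_snps_tested = sum(!is.na(scan$neg_log10_p)),
    n_cmh_undefined = attr(scan, "n_undefined"),
    ne = agg$ne, ne_replicate_medians = as.list(agg$replicate_medians),
    ne_windows_undefined = agg$n_undefined,
    cutoff = cut$cutoff, fpr = cut$fpr, n_neutral = cut$n_neutral,
    n_candidates = nrow(cand),
    n_regions = rsum$n_regions, regions_bp = rsum$total_bp,
    regions_fraction = rsum$fraction_genome,
    fixation_fraction = if (is.null(afc)) NA else afc$fixation_fraction)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
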