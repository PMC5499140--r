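---
title: "Methods: calibrated selection scans for evolve-and-resequence Pool-Seq data"
author: "erscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated selection scans for evolve-and-resequence Pool-Seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erscan)
```

## The problem

An evolve-and-resequence (E&R) experiment maintains K replicate populations,
founded from the same standing variation, under a selection regime for t
generations, and sequences pooled individuals at the founder and evolved time
points. Read counts at each SNP estimate population allele frequencies; loci
responding to selection shift consistently across replicates, while drift
produces large but replicate-idiosyncratic changes. The statistical task has
three parts: score consistent change per SNP, decide how much change drift
alone would produce, and aggregate SNP-level evidence into genomic regions,
because hitchhiking makes single SNPs unreliable markers of selection
targets.

`erscan` implements that chain on PoPoolation2-style sync files. This
vignette records the models, the tunable parameters, the numerical choices,
and what the validation does and does not establish.

## Data model and filtering

A sync file holds, per site and sample, the six counts A:T:C:G:N:del.
Coverage is defined as A+T+C+G — N and deletion reads never enter frequency
arithmetic, since frequencies are ratios of nucleotide reads. Sites are
polarized once, from the founder replicates pooled together: the major
allele is the highest summed count, the minor the second highest, ties
broken by the fixed order A < C < G < T so results are reproducible. The
same axis is reused for evolved samples, giving a single consistent
direction for frequency change. Third and fourth alleles are dropped from
the biallelic counts but retained as a per-sample "dropped" mass, so read
totals are conserved and the loss is auditable (`polarize()`).

SNP calling keeps sites where at least one founder replicate individually
shows at least `min_minor_count` minor-allele reads (default 1; base-quality
screening is a read-level property assumed upstream of count space).
Coverage trimming removes the tails of the depth distribution: the upper
threshold is the (1 − q) nearest-rank quantile of depth in the single
deepest library, the lower the q quantile of total depth over all samples
(default q = 0.01). Nearest-rank quantiles are used because depths are
integers and the thresholds should be deterministic, reportable numbers.
Masks (repeats, indel flanks) are BED intervals, 0-based half-open,
converted explicitly to the package's 1-based inclusive coordinates.
Count-level downsampling (`downsample_counts()`) thins every count
binomially with a per-library ratio `target mean / library mean`; this is
the count-space analogue of read subsampling, preserves expected
frequencies exactly, and lets two experiments be compared at equal coverage.

## The CMH scan

Each SNP forms a 2×2×K table: allele (major/minor) × time point
(founder/evolved), one stratum per replicate. The Mantel–Haenszel 1-df
chi-square with optional continuity correction is computed from the closed
form; `stats::mantelhaen.test` serves as an independent oracle in the test
suite (agreement to ten significant digits on 1000 random tables), never as
the implementation, which is vectorized over sites.

Numerical choices:

* the continuity correction defaults to on, matching the conventional
  R-dialect Mantel–Haenszel test used in Pool-Seq pipelines; it is exposed
  as a flag since either convention is defensible;
* with the correction, `|Σ deviations| ≤ 0.5` is floored to statistic 0
  (a correction should not manufacture evidence);
* strata with a zero row or column margin carry no information and are
  dropped from the sums rather than failing the site — this preserves SNPs
  with one low-coverage replicate; a site where all strata are degenerate
  gets an NA and is excluded downstream, with both tallies reported;
* p-values are computed on the log scale (`pchisq(log.p = TRUE)`), so
  −log10 p is exact far beyond the double-precision underflow point; the
  stored p-value is floored at the smallest positive double.

## Why an empirical cutoff

The CMH test models read sampling, not drift: under pure sampling its
p-values are approximately uniform (verified in the suite with enormous
pools), but over 60 generations of drift at Ne of a few hundred the null
variance of frequency change is many times the sampling variance, and the
nominal p-values become strongly anti-conservative. The package therefore
simulates a neutral cohort matched to the data — founder frequencies
resampled from the observed spectrum, observed depths resampled per time
point, the estimated Ne, the experiment's K and t — and places the cutoff at
the empirical (1 − fpr) point of the neutral −log10 p distribution
(default fpr = 0.02). The cutoff is the smallest cohort value with at most
a fraction fpr strictly above it (nearest-rank from above), and candidacy is
strict inequality; both choices make ties reproducible. The "2%" is
interpreted as a fraction of all simulated SNPs with defined tests;
undefined tests are excluded identically on both sides, which leaves the
calibration unaffected. Held-out validation (deriving the cutoff on one
cohort and measuring on an independent one) keeps the realized rate inside
the exact binomial 99% interval of the nominal rate.

## Temporal Ne estimation

Ne enters only through the neutral simulation, but it is the pipeline's most
delicate estimate. Per SNP the standardized squared change is
`Fc = (x − y)² / (z − x y)`, `z = (x + y)/2`, with x and y the founder and
evolved read frequencies; sites fixed identically at both ends
(denominator 0) are skipped and tallied. Per window of 1000 consecutive
SNPs (trailing windows under half that size are dropped) and per replicate,
the package computes:

1. **a ratio-of-sums F**: `F = Σ(x − y)² / Σ(z − x y)`. Averaging per-SNP
   Fc ratios instead is strongly upward-biased under a rare-variant-skewed
   spectrum (the denominator is tiny and noisy for rare alleles); the
   ratio-of-sums form weights SNPs by heterozygosity, and in our
   development simulations at the study conditions it removed a ~40%
   inflation of the resulting Ne;
2. **two-stage sampling corrections in chromosome units**: pooling S
   chromosomes, then sequencing to depth R, contributes sampling variance
   `p(1−p)(1/S + 1/R − 1/(SR))`, so the per-SNP effective sample size is
   `S̃ = 1/(1/S + 1/R − 1/(SR))` and the expected sampling contribution to
   F is `mean(1/S̃₀) + mean(1/S̃ₜ)`, computed with each SNP's actual
   depths and subtracted;
3. **a plan-I census term** `+ 1/(2 N_census)` for designs where the
   sequenced individuals are drawn from the breeding census population
   (plan II omits it; at a census of 1000 diploids the term moves estimates
   by under 3% anywhere in the validated range);
4. **exact drift-time inversion**: Ne solves
   `F_drift = 1 − (1 − 1/(2Ne))ᵗ` rather than the linearization
   `Ne = t/(2 F_drift)`, which overestimates noticeably once
   `t/(2Ne) ≳ 0.2` (e.g. Ne ≈ 100 at t = 60).

A non-positive corrected drift signal means the window is consistent with
infinite Ne; such windows return NA sentinels, are excluded from medians,
and are counted. Aggregation takes the median across windows per replicate
and averages the replicate medians. Design choices 1 and 4 are the
package's own, made because recovery of known truth is the operative
criterion for this estimator: across true Ne ∈ {100, 201, 285, 300, 1000}
at the experimental sampling configurations, aggregate bias stays within
±3% (acceptance suite: ±10% bands at 100 windows × 1000 SNPs).

The X chromosome is handled only descriptively: the same operations on
X-partitioned SNPs, with no ploidy rescaling inside the estimator —
X/autosome differences should emerge from the data, and candidate calling
is restricted to autosomes.

## The Wright–Fisher simulator

Loci are independent. Each generation applies genic selection
`p' = p(1+s)/(1 + s p)` (s = 0 for all null cohorts) and then drift as a
`Binomial(2 Ne, p')` draw — Ne is interpreted as diploids, so gene-copy
number is 2·Ne, the same scale as the census of 1000. Observation draws
pool composition `Binomial(S, p)/S`, a depth from the coverage model
(resampled empirical depths per time point by default, Poisson with a given
mean otherwise; depths are conditioned positive), and reads
`Binomial(R, p_pool)`. The founder is observed with the same noise model at
generation 0, because the experimental contrast is between two sequenced
samples. The suite verifies the martingale property, the closed-form drift
variance `p₀(1−p₀)(1 − (1 − 1/(2Ne))ᵗ)`, neutral fixation probabilities,
the two-stage sampling variance law, and bit-for-bit determinism under a
fixed seed.

## The synthetic-data generator

`generate_synth()` emulates the study conditions of a hot-adapted
*Drosophila simulans* E&R design: 3 replicates, 60 nonoverlapping
generations, census 1000 diploids, drift Ne 285, founder coverage ~259×,
evolved ~100×, whole-population pools of 2000 chromosomes, and a founder
spectrum Beta(0.2, 0.2) truncated to the polymorphic range of the census —
strongly skewed toward rare variants, as real founder populations are. The
default genome is deliberately desk-scale (2 chromosomes × 10 Mb, 10⁴ SNPs
per chromosome); tests use smaller configurations still, stated per test.

Planted selected loci take a position, selection coefficient, optional
starting frequency, block half-width, and a mixing weight ρ. Linkage is
emulated, not simulated: a block neighbor's final true frequency is
`clip(ρ · focal + (1 − ρ) · own neutral)`. This produces the peak-shaped
signatures that region calling needs to be tested against, with exact
ground truth, but it is **not** a recombination model: it has no genetic
map, no haplotype structure, no LD decay within or between blocks, and at
ρ = 0 every site is exchangeable with the independent-loci simulator
(tested). Passing end-to-end tests on synthetic data therefore shows the
machinery is correct and calibrated under the stated generative model; it
does not show robustness to real-data features the generator omits —
mapping artifacts, repeat regions, base-quality error, inversions
suppressing recombination over megabases, overlapping generations, or sex
chromosomes.

## Region calling

Windows of 200 kb, sliding every 100 kb, tile each chromosome from
position 1; the final, shorter window at a chromosome end is scored too
(dropping it would silently exempt telomeric candidates). The window score
is the arithmetic mean of −log10 p over **candidate** SNPs only, and is
undefined — never qualifying — when a window has no candidates: absence of
evidence cannot support selection. Averaging on the −log10 scale is the
central interpretive decision: raw p-values near 10⁻³¹ average to ~0, so a
cutoff of ~31 is only coherent for log-transformed values. Qualifying
windows (mean strictly above the cutoff) that overlap or abut are unioned
via `GenomicRanges::reduce()`; regions report window counts, unique
candidate counts, maximal window scores, summed bp and genome fraction.
Note that since every candidate individually exceeds the cutoff, a window's
candidate mean almost always does as well, so at desk scale — where 2% of
a few thousand tested SNPs scatter false positives across a toy genome —
regions can tile most of it. Region sharpness is a function of SNP density
and genome size, and comparisons should hold those fixed.

Frequency-change summaries polarize each candidate by its rising allele
(replicate-averaged change positive) and report start, end, and change
distributions plus the fraction of candidates whose final major-allele
frequency reaches 0.9 ("approached fixation").

## Defaults that matter

| parameter | default | unit | why |
|---|---|---|---|
| `min_minor_count` | 1 | reads | polymorphism call per founder replicate; quality screening is upstream |
| `coverage_quantile` | 0.01 | — | tail mass trimmed on each side of the depth distribution |
| `window_snps` | 1000 | SNPs | Ne window; SNP-count windows equalize information, unlike bp windows |
| `plan` | "I" | — | sequenced pools drawn from the breeding census |
| `fpr` | 0.02 | — | nominal false-positive rate of the empirical cutoff |
| `n_neutral` | 10⁵ | SNPs | neutral cohort; ≥ 50/fpr enforced by warning |
| `window_bp`, `step_bp` | 200000, 100000 | bp | region-scan resolution |
| `fixation_threshold` | 0.9 | frequency | "approached fixation" definition |
| continuity correction | on | — | conventional MH dialect; exposed as a flag |

## Validation scale and limitations

The acceptance checks run at 100 windows × 1000 SNPs × 3 replicates for Ne
recovery (±10% bands around truths of 285 and 201 under the two sampling
configurations) and two independent 10⁵-SNP neutral cohorts for the
held-out false-positive-rate check (exact binomial 99% interval around 2%);
property suites cover the CMH oracle equivalence, drift and sampling laws,
sync round-trips, and hand-computed region toys. All problem sizes were
chosen as the smallest that make the stochastic bands sharp.

Known limitations: the null simulator has independent loci, so the cutoff
calibration inherits the no-linkage assumption (linked drift makes neutral
exceedances locally correlated, not more frequent on average); the Ne
estimator assumes two time points and moment-based corrections rather than
likelihood; region calling is an averaging approximation, not peak
deconvolution — adjacent selection targets merge; and the linked-block
generator is a testing device, not a model of recombination.
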