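---
title: "Methods: lineage-specific enhancer priming analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-specific enhancer priming analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Background and model

Enhancers that will activate in a specific embryonic lineage are often
*primed* in the pluripotent epiblast: they carry H3K4me1 without H3K27ac,
tend to be DNA-hypomethylated and accessible, and their target genes are
preferentially up-regulated once the lineage differentiates. `epiprime`
implements a complete analysis of this phenomenon: enhancer calling, a
chromatin-state classifier, methylation/accessibility quantitation,
enhancer–gene network assignment, expression dynamics, and a donor-panel
test for naturally occurring SNPs that disrupt the primed state.

### Lineage-specific enhancer calling

A lineage-specific enhancer is an H3K27ac peak of the target tissue that
does not overlap an annotated TSS (± 200 bp) and does not overlap any
*ulterior* lineage's H3K27ac peaks (`call_lineage_specific_enhancers()`).
Where a prior enhancer catalogue exists, `subset_by_prior_annotation()`
instead retains catalogue members that overlap the focal lineage's peaks
and no other lineage's. Both filters are pure interval algebra
(`intersect_pairs()`, `subtract_near()`), built on `GRanges` and tested
against an all-vs-all brute-force oracle.

Coordinates are BED-convention (0-based half-open) at every file boundary
and in every user-facing constructor; internally intervals live in
`GRanges`. The probe-centering rule is defined in 0-based terms:
midpoint `floor((start+end)/2)`, probe
`[mid - floor(w/2), mid + ceil(w/2))`, shifted right when it would
underflow position 0 so probe length — the RPKM denominator — is constant.

### The sequential state classifier

Epiblast signal for H3K27ac, H3K4me1 and H3K27me3 is quantified as logRPKM
over 1500 bp probes centered on each enhancer (`quantify_logrpkm()`).
States are assigned by threshold rules applied in a fixed order — the first
match wins:

| order | state  | rule (human preset) | rule (mouse preset) |
|------:|--------|---------------------|---------------------|
| 1 | active   | H3K27ac > 2.97 | H3K27ac > 1.2  |
| 2 | poised   | H3K27me3 > 2   | H3K27me3 > 1.25 |
| 3 | primed   | H3K4me1 > 1.2  | H3K4me1 ≥ 0.4  |
| 4 | inactive | otherwise      | otherwise      |

All comparisons are strict except the mouse primed rule, which is
inclusive (`primed_inclusive` in `state_thresholds()`). The thresholds are
configuration, not constants: absolute logRPKM depends on upstream read
processing, so a user recalibrating on their own quantitation should
adjust them (the presets are carried as named defaults). Probe counts are
floored at one read before the log so values stay finite; the floor is the
`pseudocount` argument.

Subgroups (`select_subgroups()`): all primed records are **ePrimed**, all
poised **ePoised**; from the inactive class, the
`min(|ePrimed|, |inactive|)` records with the lowest epiblast H3K4me1
become **eNon-primed** (the similarly-sized contrast group), and the rest
are **intermediate**. Ties at the cutoff rank break by (chrom, start)
ascending, for determinism. We treat poised separately from intermediate
rather than folding it in; the two interpretations differ only in the
heatmap-style presentation, and keeping ePoised separate preserves the
state partition.

### Methylation, accessibility, conservation

`methylation_rate()` is the coverage-weighted bisulfite rate
(100·Σmeth/Σtotal) over CpGs in a 500 bp core probe, with a per-CpG-mean
alternative behind a flag (quantitation tools differ here and neither mode
is universally standard); `min_calls` defaults to 1 (no coverage filter at
probe level). `global_methylation()` tiles the genome in non-overlapping
10 kb windows, takes each window's weighted rate, and averages windows with
equal weight; the step size equals the window because a sliding step is
not needed for a global summary. Accessibility profiles use
`profile_running_average()` (50 bp windows) and `aggregate_profiles()`
(mean ± population SD across donors); conservation uses
`average_score_over_probe()` over a 1 kb probe, excluding undefined bases
from the denominator.

### Enhancer–gene networks and expression dynamics

`assign_enhancers()` implements the hybrid promoter-capture Hi-C +
proximity model: a gene–enhancer edge exists if the enhancer overlaps a
promoter-interacting fragment whose bait maps to the gene, or if the gap
between the enhancer edge and the gene's TSS is ≤ 20 kb. The TSS is the
anchor for distance because it is the regulated element; a bait naming
several genes yields edges to all of them. `filter_exclusive()` keeps
genes touching exactly one (lineage, subgroup) group. Enrichment
(`enrich()`) is a local one-sided hypergeometric test against user-supplied
GMT libraries with BH adjustment reported alongside the raw p — no web
service involved. No expression filter is applied to proximity edges; the
exclusivity filter is the only pruning step.

Expression dynamics: `percentile_rank()` converts expression to percentile
position within each tissue (mid-rank ties, `(rank−1)/(n−1)·100`, so the
top gene is 100 and a fully tied column is 50); `group_fold_change()` is
`2^(median_target − median_reference)` over a gene group, matching a
box-plot median presentation (a mean-based contrast is a one-line change
but the median is what the plots show); `welch_t()` treats the genes of a
group as observations; `anova_oneway()` is the classic pooled-variance F
used for per-enhancer methylation comparisons between subgroups. Degenerate
inputs (zero variance everywhere, all-identical groups) are reported as
no-difference (p = 1) with a message rather than an error, since they arise
naturally in tiny planted fixtures.

### Priming-altering SNPs in donor panels

Per donor, replicate ATAC peak sets are collapsed to high-confidence peaks
supported by ≥ 2 replicates at per-base resolution
(`high_confidence_peaks()`). For each SNP inside an ePrimed enhancer,
donors split into alt-carriers (het or hom-alt — "SNP present") versus
hom-ref; `detect_priming_alteration()` calls a **gain** when every alt
carrier has a high-confidence peak over the enhancer and no hom-ref donor
does, **loss** for the mirror, **none** for any discordance, and
**untestable** when either group has < 2 genotyped donors. Unanimity is a
deliberately conservative call rule: with small donor groups a single
discordant donor is better read as "no call" than as evidence. Donors
carrying a second SNP in the same enhancer can be excluded
(`exclude_confounded`).

Motif annotation is PWM scanning (`scan_motifs()`): log-odds against a
background, both strands, hit threshold 0.8 × the maximum achievable score
per PWM (configurable per PWM — fixed database-specific thresholds are not
portable), `N` bases scoring zero. SNP effects on motifs are classified as
introduced / ablated / swapped / weakened / strengthened with a 1-bit
tolerance for score shifts — roughly the cost of one preferred-base
substitution. The association between motif membership and altered
accessibility is a per-motif two-sided Fisher exact test with the sample
odds ratio (Haldane-corrected at zero cells); raw p at 0.05 is the
headline threshold with BH-adjusted values reported alongside. Calls are
made per (enhancer, SNP) pair; when several SNPs share an enhancer each
pair is tested separately.

## The synthetic data generator

`generate_fixture()` produces every input the pipeline reads, with planted
ground truth serialized next to the data and never consumed by the pipeline
under test. Its defaults are the study conditions the package is tested
under:

* 2 lineages × 300 enhancers on a 2 × 1 Mb genome — the order of magnitude
  of real lineage-specific enhancer sets; 27% primed, 10% active, 10%
  poised, the rest inactive.
* Mark logRPKM drawn from per-state Gaussians (SD 0.3) whose means sit
  ≥ 3 SD from every classifier threshold, with draws truncated at 3 SD so a
  planted state can never cross a decision boundary; emitted coverage
  tracks quantize counts to whole reads, and ground-truth subgroup labels
  are derived from the quantized values so end-to-end recovery is exact.
* Methylation beta-binomial per CpG: 25% at primed cores vs 75%
  elsewhere (~8× coverage); every generated fixture asserts the planted
  hypomethylation contrast before returning.
* 75% of each ePrimed/eNon-primed subgroup linked to a dedicated gene by a
  PCHiC interaction; genes linked to ePrimed enhancers gain a 0.93 log2
  (~1.9-fold) expression effect in their lineage. Baseline expression is
  N(5, 1) per gene with small residual noise (SD 0.03 log2): the
  difference-of-medians estimator carries sampling noise from the baseline
  spread itself, and with ~60 linked genes this noise level keeps the
  planted effect recoverable within a few percent. TSS sit > 20 kb from all
  enhancers so gene links flow only through the planted interactions,
  keeping exclusivity labels exact; proximity edges are exercised by unit
  tests instead.
* A 10-donor panel, 3 ATAC replicates each, 5% replicate peak dropout; 6
  causal SNPs placed inside embedded consensus instances of one designated
  PWM (alternate allele = the worst base, which ablates the motif and
  removes the peak for alt carriers), plus 30 genotype-independent SNPs,
  half inside instances of other motifs.

What the generator does **not** emulate: read-level noise (no FASTQ),
irregular peak shapes, copy-number or mapping artefacts, correlated
methylation along chromosomes, inter-donor covariance, or realistic motif
co-occurrence. Passing tests therefore demonstrate the correctness of the
algorithms under the stated statistical structure, not robustness to every
artefact of real sequencing data.

`generate_null_panel()` builds panels in which accessibility is independent
of genotype, used to measure the type-I error of the motif association.
Calibration uses 4000 testable SNPs per panel with minimal 2-vs-2 donor
groups and fair-coin accessibility: Fisher's exact test is conservative for
discrete tables, and at smaller panel sizes (hundreds of SNPs) its measured
size is 0.038–0.045 rather than 0.05 — a known property of the test, listed
below as a limitation. At genome-scale counts the discreteness is
negligible and the measured size is nominal.

## Numerical choices and degenerate inputs

* Probe counts floored at `pseudocount = 1` read before `log2`.
* PWM probabilities floored at 1e-6 when forming log-odds, so absent bases
  stay finite; `N` contributes zero.
* Fisher p comes from exact hypergeometric enumeration
  (`stats::fisher.test`); the odds ratio reported is the sample OR `ad/bc`
  (not the conditional MLE), Haldane-corrected (+0.5/cell) at zero cells.
* Welch/ANOVA degenerate inputs → p = 1 with a message (see above).
* `make_probe` midpoint uses `floor`, making odd-width probes
  deterministic; eNon-primed rank ties break by (chrom, start).
* All generator randomness flows from the single `seed` in
  `fixture_config()`; the generator and null-panel builder save and restore
  the caller's RNG state.

## Problem sizes used in the shipped checks

The test-suite and `scripts/acceptance.R` run entirely on generated data:
default-scale fixtures (600 enhancers, 300 genes, 36 SNPs) for end-to-end
recovery, reduced fixtures (80 enhancers) when a property is checked across
many seeds, 1000 random instances for the interval-engine oracle, 10,000
draws/replicates for classifier and type-I calibration, and 100 null panels
of 4000 SNPs for the association calibration. These sizes were chosen to
make Monte-Carlo bands tight relative to the contracts being checked.

## Known limitations

* Absolute logRPKM values depend on upstream processing; the shipped
  thresholds are presets to be recalibrated per dataset.
* Fisher's exact test is conservative at small panel sizes (above).
* The unanimity call rule has low sensitivity with many donors per group —
  it trades recall for precision and is configurable via `min_group`.
* The pipeline's resume-from-disk caching hashes the whole input set: any
  input change reruns all stages (per-stage dependency tracking is not
  implemented).
* `run_all()` expects the fixture directory layout of `write_fixture()`;
  real data must be arranged in that layout (standard formats throughout).
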