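# epiprime

Analysis of **epigenetic enhancer priming**: enhancers that will activate in
a specific embryonic lineage often already carry a distinctive chromatin
state in the pluripotent epiblast — H3K4me1 without H3K27ac, DNA
hypomethylation, and open chromatin. `epiprime` provides a tested, reusable
R implementation of this analysis for epigenomics researchers working with
ChIP-seq/CUT&Tag peaks, bisulfite methylation calls, promoter-capture Hi-C
interactions, expression matrices, and donor ATAC-seq panels.

The pipeline:

1. **Lineage-specific enhancer calling** — H3K27ac peaks of a tissue that
   overlap neither an annotated TSS (± 200 bp) nor any other profiled
   lineage's peaks.
2. **Sequential chromatin-state classification** from epiblast logRPKM over
   1500 bp enhancer-centered probes, first rule wins:
   *active* (H3K27ac > 2.97) → *poised* (H3K27me3 > 2) → *primed*
   (H3K4me1 > 1.2) → *inactive* (human preset; a mouse preset ships too).
   Subgroups: **ePrimed** (all primed), **ePoised**, **eNon-primed** (the
   equally-sized lowest-H3K4me1 slice of the inactive class), and
   **intermediate**.
3. **Methylation / accessibility quantitation** — coverage-weighted CpG
   methylation over 500 bp cores, 10 kb-window global levels, 50 bp
   running-average accessibility profiles.
4. **Enhancer–gene networks** — promoter-capture Hi-C overlap plus ≤ 20 kb
   promoter proximity, exclusivity filtering, and local hypergeometric
   gene-set enrichment (GMT libraries).
5. **Expression dynamics** — percentile ranks, median fold changes
   (2^Δmedian), Welch's *t*, one-way ANOVA.
6. **Priming-altering SNPs** — per-donor replicate-consensus ATAC peaks,
   genotype-stratified gain/loss calls at ePrimed enhancers, PWM motif
   scanning with ref/alt effect classification (introduced / ablated /
   swapped / weakened / strengthened), and per-motif Fisher exact
   association between motif membership and altered accessibility.

A seeded synthetic multi-omic generator (`generate_fixture()`) emits every
input format the pipeline reads (narrowPeak, bedGraph, methylation TSV,
BED, PCHiC TSV, expression TSV, GMT, JASPAR pfm, FASTA, VCF) with planted
ground truth, so the whole analysis is testable without external downloads.

## Worked example

```r
library(epiprime)

fx_dir  <- tempfile("fixture"); out_dir <- tempfile("run")
bundle  <- generate_fixture(fixture_config(seed = 11), dir = fx_dir)
results <- run_all(pipeline_config(fx_dir, out_dir, species = "human",
                                   seed = 11))
results$priming
#>   lineage n_enhancers priming_fraction
#> 1     hME         300               27
#> 2    hNPC         300               27
results$expression
#>              group n_genes fold_change    log2_fold           t       df            p stars
#> 1     hNPC|ePrimed      61   1.8759620  0.907630639  5.27794340 119.9998 5.890186e-07   ***
#> 2 hNPC|eNon-primed      59   0.9818956 -0.026358492 -0.02480087 115.9997 9.802564e-01
#> 3      hME|ePrimed      61   1.9072062  0.931460849  4.95252824 119.9999 2.423642e-06   ***
#> 4  hME|eNon-primed      60   0.9939565 -0.008745329  0.01554351 117.9989 9.876248e-01
```

Reading the output: 27% of each lineage's enhancers are classified primed
in the epiblast; genes linked **exclusively** to ePrimed enhancers are
up-regulated ~1.9-fold in their lineage (Welch's *t* against the epiblast,
`***` p < 0.001), while eNon-primed-linked genes are flat. The variant
stage (`results$variants$associations`) ranks the motif whose disruption
flips accessibility as the top Fisher association, and
`results$methylation` shows hypomethylated ePrimed cores (~26%) against the
~75% background with a significant subgroup ANOVA. Per-stage TSVs, BED
files per subgroup, `summary.json` and a `run_manifest.json` (content hash;
unchanged reruns resume from disk) land in `out_dir`.

A thin CLI wrapper is included for shell use:

```sh
Rscript inst/cli/epiprime.R simulate --seed 1 --out fixture/
Rscript inst/cli/epiprime.R run-all --fixture fixture/ --out results/
```

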