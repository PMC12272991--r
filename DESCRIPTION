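Package: epiprime
Title: Lineage-Specific Enhancer Priming Analysis from Multi-Omic Chromatin Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls lineage-specific enhancers from H3K27ac peak sets, classifies
    their epiblast chromatin state (active, poised, primed, inactive) from
    H3K27ac/H3K4me1/H3K27me3 signal with a sequential threshold classifier,
    quantifies DNA methylation and accessibility over enhancer-centered probes,
    links enhancers to genes through promoter-capture Hi-C plus promoter
    proximity, tests lineage-restricted expression dynamics of the linked gene
    groups, and associates naturally occurring SNPs in donor panels with
    disruption of the primed state via genotype-stratified accessibility and
    per-motif Fisher tests. Includes a seeded synthetic multi-omic fixture
    generator with planted ground truth so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
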