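Package: methdiffscan
Title: Differential CpG Methylation Analysis for Whole-Genome Bisulfite
    Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide differential CpG methylation analysis for
    whole-genome bisulfite sequencing (WGBS) count data. Tests single
    cytosines (DMCs), 1-kb tiled regions (DMRs) and TSS +/- 1 kb promoters
    (DMPs) between two groups with a binomial logistic-regression
    likelihood-ratio test on methylated/unmethylated read counts, adjusts
    p-values for false discovery, annotates loci to their nearest
    transcription start site, derives gene-level statistics (top-DMC genes,
    high-frequency DMC genes, chromosome-wise hyper/hypo distributions,
    set overlaps), correlates promoter-proximal methylation change with
    expression fold changes, and performs Fisher-exact gene-set enrichment.
    Includes a WGBS count simulator with a planted-effect ground-truth
    ledger for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
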