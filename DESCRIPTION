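Package: svcellreg
Title: Cohort Structural-Variant Callsets and Cell-Type-Resolved Expression Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a high-confidence cohort structural-variant (SV) callset
    from multiple long-read callers and links SVs to cell-type-resolved gene
    expression. Implements multi-stage ensemble merging of per-sample,
    per-caller SV calls; region masking, read-evidence and linkage-
    disequilibrium quality metrics with a low-confidence filter; strict and
    lenient SV matching with precision/recall benchmarking; width-preserving
    permutation enrichment against annotation features; haplotype partitioning
    of long reads at phased heterozygous SNPs to phase SV genotypes;
    pseudobulk expression processing with batch and surrogate-variable
    adjustment; cis-SV-eQTL regression and beta-binomial allelic-imbalance
    testing with cell-type-specificity classification; and a synthetic-data
    generator producing every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    vcfR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
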