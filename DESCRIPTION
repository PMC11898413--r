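Package: rodscan
Title: Selective-Sweep Scans from Windowed Diversity, Differentiation and
    Reduction-of-Diversity Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reduction-of-diversity (ROD) selective-sweep scans in
    multi-population whole-genome resequencing cohorts. Reads multi-sample VCFs
    into a genotype-dosage model, applies minor-allele-frequency, depth and
    missingness filters, computes sliding-window nucleotide diversity,
    Weir-Cockerham fixation index and Tajima's D, screens for sweeps as joint
    top-quantile outliers of windowed Fst and ROD against a designated
    reference population, merges outlier windows into regions and annotates
    overlapping genes, and infers population structure via identity-by-state
    neighbor-joining trees and an admixture-model EM with cross-validation
    across K. A seeded Balding-Nichols cohort simulator with implanted sweeps
    provides ground truth for end-to-end verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    vcfR,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
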