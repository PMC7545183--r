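Package: feralscan
Title: Population-Genomic Scans for Crop De-Domestication and
    High-Altitude Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for detecting de-domestication and
    high-altitude adaptation signals in resequenced crop cohorts, built
    around hexaploid wheat. Implements windowed Weir-Cockerham FST and
    nucleotide-diversity scans with a label-shuffling permutation null,
    read-depth normalisation with presence-absence variation (PAV) and
    CNV-index calling, soft-clip read genotyping of transposable-element
    insertions, gene-haplotype classification into high- versus
    low-altitude classes, mixed-linear-model association with kinship and
    principal-component covariates (including structural-variant
    pseudo-genotypes and chromosome-local structure correction), and
    probe-read anchoring of scaffolds into pseudomolecules. A synthetic
    cohort generator with known ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
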