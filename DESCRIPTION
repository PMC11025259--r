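Package: wexscape
Title: Post-Variant-Calling Analysis of Tumor Whole-Exome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of somatic variant and
    allele-specific copy-number calls from tumor whole-exome sequencing
    cohorts: mutation burden and class accounting, 96-context mutational
    spectra with COSMIC-style signature refitting and de-novo NMF
    extraction, genomic-scar homologous recombination deficiency scores
    (LOH, TAI, LST), cancer-cell-fraction based clonality and intratumor
    heterogeneity, gene-level copy-number alteration frequencies,
    actionability tiering against a bundled knowledge base, and
    subtype-adjusted two-cohort comparison with FDR control. Includes a
    synthetic cohort generator with known ground truth so every stage is
    testable by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
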