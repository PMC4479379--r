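Package: genemiss
Title: Estimation of Undetected Genes in RNA-Seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-parametric estimation of the number of expressed genes that
    were missed by an RNA-seq sample, from the sample's frequency-of-frequencies
    spectrum. Implements the harmonic estimator of degree 6 (h6) together with
    the classical Chao1, bias-corrected Chao2, iChao1 and Medial richness
    estimators; parametric bootstrap standard errors and approximate confidence
    intervals; an estimator-selection harness that scores candidate estimators
    against known truth on complete samples; formulas for the extra sequencing
    depth needed to detect a chosen proportion of the missing genes; and
    known-truth synthetic transcriptome generators for validation. Count tables
    (TSV/CSV, one row per gene, one column per library) and bare frequency
    spectra are accepted as input; a command-line interface is provided for
    shell use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
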