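Package: symbiokern
Title: Consensus Differential Expression and Symbiont Quantification for
    Cnidarian-Dinoflagellate Transcriptomics
Version: 0.1.0
Authors@R:
    person("Symbiokern", "Developers", email = "symbiokern@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-color microarray and qPCR studies of
    symbiotic versus aposymbiotic sea anemones. Implements GenePix-style scan
    ingestion, background correction with a positive offset, print-tip loess
    within-array and quantile between-array normalization, empirical-Bayes
    moderated statistics (M and B log-odds), a per-individual consensus
    ("Kern") gene-set selection rule, dual-design epidermis/gastroderm
    tissue-specificity assignment, Fisher's exact GO-term enrichment,
    Cluster-3.0-style specimen clustering, and qPCR standard-curve
    quantification of symbiont:host nuclei ratios, geNorm-style reference-gene
    stability, and calibrator-relative expression. Ships a synthetic-data
    generator with planted ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
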