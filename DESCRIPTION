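Package: spermage
Title: Male Age, the Sperm Methylome and Assisted Reproduction Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline linking male age to sperm DNA
    methylation and assisted-reproduction (ART) outcomes. Provides per-CpG
    epigenome-wide association models on M-values with dual-scale effect
    reporting, adjacent-site correlation clustering of array probes into
    co-methylated regions, generalized-estimating-equation tests for
    differentially methylated regions, interval-based genomic annotation and
    Fisher-exact feature enrichment, oocyte-weighted logistic models of ART
    outcomes, and a high-dimensional mediation estimator (sure independence
    screening, minimax concave penalty, leave-one-out stability selection,
    rescaled natural indirect effects) of the proportion of the male-age
    effect transmitted through sperm methylation. Includes a synthetic cohort
    generator with known ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp,
    GenomicRanges,
    BiocGenerics,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomeInfoDb
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
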