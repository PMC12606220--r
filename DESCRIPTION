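Package: zoomsphylo
Title: Collagen Peptide-Mass-Fingerprint Screening and Amino-Acid Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ZooMS-style analysis of ancient bone collagen: in-silico
    tryptic digestion of type I collagen (COL1A1/COL1A2) with hydroxyproline and
    deamidation modifications, MALDI-ToF peak-list matching and marker-panel
    taxon identification, collagen preservation and deamidation scoring,
    assembly of peptide-derived amino-acid alignments with missing-residue
    masking, maximum-likelihood phylogenetics under empirical amino-acid models
    with invariant sites and free-rate categories (including nonparametric
    bootstrap and the approximately unbiased topology test), and Bayesian node
    dating under a relaxed lognormal clock with a birth-death tree prior and
    uniform fossil calibrations. Includes a forward simulator that generates
    birth-death trees, collagen-like alignments, tryptic-peptide spectra and
    age-dependent deamidation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    knitr,
    rmarkdown,
    mzR,
    yaml,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
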