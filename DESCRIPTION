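Package: clineCoCo
Title: Cline Coincidence-Concordance Analysis and FST Outlier Scans Along
    Geographic Transects
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for distinguishing diversifying selection from demographic
    history in one-dimensional genetic clines. Provides automated per-locus
    cline detection by maximum-likelihood twice-broken-stick fits against a
    horizontal null, genomic Co-Co (coincidence/concordance) outlier analysis
    via cross-validated two-dimensional kernel densities with highest-density
    envelopes, an fdist-style FST outlier test backed by a finite-island
    structured-coalescent null with infinite-alleles mutation, and a
    secondary-contact stepping-stone coalescent simulator for assessing how
    much clinality neutral history alone produces. Includes readers and
    writers for tabular allele-frequency data and GenePop genotype files,
    Hardy-Weinberg genotype synthesis, Weir-Cockerham FST estimation, Mantel
    tests, and synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
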