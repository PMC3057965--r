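Package: jicim
Title: Joint Inclusive Composite Interval Mapping for Nested Association
    Mapping Populations
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint QTL linkage mapping for multi-family populations that
    share one common parent (nested association mapping, NAM, designs).
    Implements the two-step JICIM procedure: stepwise selection of
    family-nested marker cofactors under a general linear model, followed
    by a one-dimensional interval scan that fits an F+1-mean, F-variance
    normal mixture by EM on cofactor-adjusted phenotypes. Includes
    single-family inclusive composite interval mapping (ICIM) as the F=1
    special case, per-family recombination estimation on a consensus map,
    missing-genotype imputation, phenotypic-variance-explained summaries,
    residual-permutation and genome-wide k-error-rate (GWER(k)) thresholds,
    a NAM genotype/phenotype simulator, and a detection-power evaluation
    harness with support-interval scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Genetics, QTL, LinkageDisequilibrium, Software
RoxygenNote: 7.3.3
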