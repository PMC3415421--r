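Package: rvth
Title: Trend and Heterogeneity Test and Comparators for Rare-Variant
    Association with Binary Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-level association tests between rare variants (minor
    allele frequency below 0.5%) and binary traits with covariates: the
    trend-and-heterogeneity (TH) test on Pearson residuals with
    resampling inference, logistic regression on carriage status (with
    and without covariates), the C-alpha extra-binomial variance test
    (asymptotic and permutation), and a SKAT-type variance-component
    score test (mixture-of-chi-square asymptotics and parametric
    bootstrap). Includes a liability-threshold case-control simulator
    with Wright's stationary allele-frequency distribution,
    deleteriousness classes and signed heterogeneous effects, plus an
    experiment harness for empirical size and power grids, and VCF/TSV
    readers and writers for applying the tests to external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
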