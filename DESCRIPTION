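Package: halfsibqg
Title: Quantitative Genetics of Nested Half-Sib Common-Garden Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative-genetic analysis of nested full-sib,
    half-sib breeding designs reared in common-garden experiments, with a
    focus on early life history traits of salmonids and the role of egg size
    as a maternal-effect trait. Provides derived-trait computation (yolk sac
    volume, conversion efficiency, degree-day growth rates), REML
    variance-component models fit before and after an egg-size covariate,
    heritability and maternal-effect estimation with within-family bootstrap
    and bias-corrected accelerated (BCa) confidence intervals,
    simulation-based restricted likelihood ratio tests for variance
    components, fixed-effect variance partitioning, phenotypic divergence
    rates in haldanes, multivariate population differentiation (nMDS,
    PERMANOVA, dispersion homogeneity, Mantel tests), and a synthetic-data
    generator that reproduces the statistical structure of a three-population
    hatchery experiment with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    car,
    emmeans,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    boot,
    yaml
Config/testthat/edition: 3
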