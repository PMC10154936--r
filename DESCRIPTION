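Package: ecosel
Title: Ecotype Divergence, Trait Allometry and Seed-Mass Selection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for studying ecotypic divergence and local
    adaptation in perennial grasses from common-garden and reciprocal
    seed-addition experiments. Provides canonical discriminant analysis of
    genotype-mean life-history traits, nested random-effects variance
    partitioning with case-bootstrap confidence intervals, AICc all-subsets
    selection and full model averaging of climate-of-origin effects on seed
    mass, standardized major axis (SMA) allometry with among-ecotype
    common-slope tests, Poisson generalized linear models of seedling and
    adult recruitment, and a joint hierarchical Bayesian Poisson model that
    estimates site-specific selection gradients on seed mass with correlated
    plot effects. A synthetic-data generator with known truth mirrors the
    diversity-panel and field designs so that every stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
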