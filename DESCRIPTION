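Package: telometa
Title: Multilevel Phylogenetic Meta-Analysis of Parental-Age Effects on
    Offspring Telomere Length
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysing parental age at conception effects on
    offspring telomere length across vertebrates.  Converts heterogeneous
    reported statistics (regression slopes with standard errors or confidence
    intervals, t statistics, correlation coefficients) into Fisher's-z effect
    sizes with known sampling variances, fits multilevel random-effects
    meta-regression models with study, estimate, and phylogenetically
    correlated species random effects by maximum likelihood or REML, and
    decomposes heterogeneity (I-squared) across variance components.
    Includes omnibus and likelihood-ratio tests, post-hoc marginal-means
    contrasts, per-moderator marginal R-squared, modified Egger's regression
    and time-lag publication-bias diagnostics, contour-enhanced funnel and
    forest plots, and a synthetic-data generator that reproduces the assumed
    data-generating process so the entire pipeline can be validated by
    simulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    car,
    emmeans,
    knitr,
    metafor,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
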