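Package: climanemia
Title: Temperature-Attributable Childhood Anemia Burden Under Climate Change Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for climate-health attribution of childhood
    anemia in low- and middle-income settings. Estimates the association
    between annual mean temperature and childhood anemia prevalence with
    mixed-effects logistic regression on clustered survey microdata, converts
    odds ratios to risk ratios given outcome prevalence, decomposes the effect
    through malnutrition and malaria mediators by difference of coefficients
    with bootstrap confidence intervals, bias-corrects climate-model
    temperature ensembles against a reference series by additive (delta)
    scaling, and projects excess anemia cases per 100,000 person-years under
    emission scenarios with Monte Carlo empirical confidence intervals. A
    seeded synthetic-data module generates survey microdata, gridded daily
    climate fields, pseudo-GCM ensembles, city boundaries and population
    grids with known generating parameters so every stage is testable
    end-to-end without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    rlang,
    sandwich,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
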