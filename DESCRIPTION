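Package: scalechron
Title: Scale-Increment Biochronologies and Bayesian Growth Models for Sea Trout
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for sclerochronology analyses of anadromous brown trout
    (sea trout) scale-increment data: parsing and filtering of annual
    growth-zone records, synthetic cohort generation with known generative
    parameters, a Bayesian Gaussian linear mixed model of log increment width
    with crossed random intercepts (fish and group-by-environment-by-year)
    fitted by a blocked Gibbs sampler under penalized-complexity, half-Cauchy
    or inverse-gamma variance priors, DIC model comparison, growth
    biochronology extraction, variance partitioning, a wild-versus-hatchery
    plasticity variance-ratio test, and Monte Carlo correlation tests between
    growth chronologies and temperature that propagate posterior uncertainty.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
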