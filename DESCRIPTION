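Package: fgmtools
Title: Analysis of Fast-Growth Alchemical Solvation Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for unidirectional nonequilibrium
    (fast-growth) alchemical solvation free-energy calculations. Provides
    work-distribution estimators (Jarzynski, Crooks-Gaussian, and the
    stage-convolution Jarzynski estimate) with an Anderson-Darling
    normality-gated decision tree, analytic and bootstrap 95% confidence
    intervals, assembly of 1-octanol/water partition coefficients (LogP)
    and transfer free energies, benchmark metrics (Lin's concordance
    correlation, Pearson and Kendall correlation, mean unsigned/signed
    error, best-fit line), conformer charge-set arithmetic, and a seeded
    synthetic work-ensemble generator with closed-form exact free energies
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
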