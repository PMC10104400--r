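Package: twinsleep
Title: Twin Modeling of Adolescent Sleep-Wake Behaviors from Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for classical twin analyses of actigraphy-derived
    sleep phenotypes in adolescents. Provides synthetic twin-cohort and
    arm-angle actigraphy generators with known ACE structure, nightly
    sleep-phenotype extraction (onset, wake, duration, midpoint, restorative
    sleep), preprocessing (night filtering, winsorization, covariate
    residualization), maximum-likelihood univariate ACE/AE/CE/E
    variance-component models with AIC comparison and profile-likelihood
    confidence intervals, and bivariate Cholesky and constrained
    independent-pathway decompositions with genetic, shared-environmental and
    unique-environmental correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
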