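Package: pkeval
Title: External Evaluation of Population Pharmacokinetic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the external evaluation of population pharmacokinetic
    models against sparse, opportunistically sampled concentration data.
    Represents joint parent-metabolite compartmental models with log-normal
    inter-individual variability, finite-mixture (metabolizer subpopulation)
    clearances, allometric covariate scaling and per-analyte residual error;
    solves them analytically for arbitrary oral dosing histories; simulates
    replicate study datasets; and computes the standard evaluation battery:
    prediction-based bias and precision metrics (PE, RMSE, MPE, MAPE),
    empirical-Bayes individual estimates with mixture-class posteriors,
    conditional weighted residuals, prediction-corrected visual predictive
    checks, and normalized prediction distribution errors with their
    hypothesis tests. Includes a generator of synthetic opportunistic
    pediatric cohorts so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
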