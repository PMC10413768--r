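Package: pedree
Title: Pediatric Resting Energy Expenditure Equations and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting and validating resting energy expenditure
    (REE) in children and adolescents. Encodes fourteen published pediatric
    REE prediction equations (WHO, Schofield, IOM, Kim, Henry, Molnar,
    Mueller, Derumeaux-Burel, Schmelzle, Tverskaya, Lazzer, and a fat-free
    mass based equation) with per-equation sex and age dispatch and energy
    unit normalisation; computes the standard method-agreement statistic
    suite (accurate-prediction percentage, bias percent, RMSE, Bland-Altman
    limits of agreement) overall and stratified by BMI group and sex;
    derives new equations by univariate screening followed by backward
    stepwise ordinary least squares; classifies weight status from LMS
    BMI-for-age references; and simulates calibrated synthetic cohorts so
    the whole pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
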