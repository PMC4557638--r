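Package: euireclass
Title: Reclassification of External-Cause Deaths of Undetermined Intent
Version: 0.1.0
Authors@R:
    person("Maintainer", "euireclass", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Indirect statistical reclassification of deaths coded as
    "event of undetermined intent" (ICD-10 Y10-Y34) into non-transport
    accidents, suicides, and homicides. Fits sex-stratified, class-weighted
    multinomial logistic models on deaths with known external causes,
    assigns causes to undetermined deaths under a minimum estimated
    classification probability (ECP) threshold, performs a
    misclassification-matrix population-level adjustment of the full set of
    undetermined deaths, checks coefficient robustness by parametric
    perturbation, and computes age-standardized death rates for official,
    reclassified, and adjusted cause-specific mortality. Includes a
    synthetic death-record microdata generator with a configurable
    masking mechanism so the whole pipeline can be validated against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
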