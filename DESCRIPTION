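Package: impactdm
Title: Discrete-State Markov Projection of Type 2 Diabetes Prevalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time Markov cohort model for projecting the prevalence
    of type 2 diabetes in an adult population from baseline risk-factor and
    disease prevalence surveys, in the tradition of the MEDCHAMPS IMPACT
    family of policy models. The population is partitioned into mutually
    exclusive exposure states (healthy, obese, smoker, obese smoker), a
    diabetes state with no remission, and two absorbing death states.
    Includes an illness-death ("DisMod"-style) back-calculation of incidence
    and diabetes-related excess mortality from a cross-sectional prevalence
    curve, Barendregt partitioning of all-cause mortality by relative risk,
    risk-factor trend rules with caps, counterfactual prevention-program
    scenarios, demographic interpolation and denominator reconstruction from
    published report tables, a synthetic-country generator with analytic
    ground truth for validation, and report tabulation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
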