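Package: enbal
Title: Energy-Balance Modelling for Weight-Reduction Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core for mobile and workplace weight-reduction
    programs built on energy balance: resting metabolic rate from
    fat-free mass (Cunningham equation), IPAQ-SF MET-minute activity
    scoring, total energy expenditure, individualized calorie
    prescription with periodic goal resetting and sex-specific safety
    floors, diet and activity tracking with daily balance feedback,
    eligibility screening, achievement scoring and tie-aware rankings,
    CT Hounsfield-window adipose-area quantification, a synthetic
    cohort simulator, and paired pre/post analysis with an exact
    Wilcoxon signed-rank test.
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
    jsonlite,
    yaml,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
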