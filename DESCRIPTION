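Package: smileval
Title: Validation Pipeline for Rated Facial-Expression Stimulus Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing forced-choice
    rating studies of facial-expression stimuli, with an emphasis on
    functionally distinct smile types (reward, affiliative, dominance)
    alongside disgust and neutral expressions. Provides a machine-readable
    registry of action-unit (FACS) expression prototypes, a Latin-square
    counterbalanced design generator, a simulator for multi-rater
    categorical and ordinal rating data, chance-corrected recognition
    metrics (simple and unbiased hit rates, Wagner's chance level, the
    arcsine square-root transform), interrater reliability statistics
    (Fleiss' kappa, two-way intraclass correlations), composite expressor
    rankings, and noncentral-F power analysis for mixed-design
    repeated-measures ANOVA interactions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
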