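Package: penchoice
Title: Preference Analysis for Free-Access Housing Trials in Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing free-access housing preference trials in
    which animals (here, gilts choosing between individual stalls and a
    shared open pen) are scan-sampled hourly over several days. Provides
    per-animal two-state Markov-chain time-budget inference with
    simulation-based 95 percent confidence intervals tested against an
    area-proportional null occupancy, scan-sampling quality control
    (Cohen's kappa, sampling-rate chi-square), open-field/novel-object
    personality scoring by unrotated principal component analysis with
    adequacy checks and iterative-PCA imputation, mixed-effects logistic
    models of hourly occupancy, proportional-odds models of preference
    class on trait scores, and a seeded synthetic-data generator that
    reproduces the statistical structure of such trials for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
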