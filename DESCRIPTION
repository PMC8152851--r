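Package: glossperm
Title: Gloss Discrimination Psychophysics and Gloss-Selective Unit Analysis
Version: 0.1.0
Authors@R:
    person("Mika", "Ito", email = "glossperm@example.org", role = c("aut", "cre"))
Description: Tools for linking gloss-selective neural activity to gloss
    discrimination behavior. Builds gloss stimulus parameter ladders in the
    perceptual c-d space and factorial task condition grids, classifies
    multiunit recording sites as gloss-selective using ANOVA, tuning-curve
    correlation and a shuffled-image luminance control, fits two-parameter
    logistic psychometric functions to binary gloss choices, tests
    microstimulation-induced psychometric shifts with a within-session
    permutation test, and summarizes muscimol inactivation slope changes
    across post-injection time points and repeated injections. Ships a
    seeded synthetic-data generator with known ground truth so every stage
    of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
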