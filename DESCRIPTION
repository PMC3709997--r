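Package: amphidisp
Title: Stage-Biased Dispersal Inference for Intertidal Amphipod Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers stage-biased dispersal of intertidal amphipods from paired
    plankton-net (swimmer) and sediment-core (mud resident) surveys. Implements
    the full inference chain: sample normalization (Folsom subsample expansion,
    volume and area standardized densities, length-weight biomass), a fully
    random three-factor ANOVA (Site, Round, Night nested in Round) with quasi-F
    ratios and variance components, bootstrap comparison of swimmer versus
    resident size distributions with trimmed percentile confidence limits,
    G-tests of adult stage structure with category pooling, reduced major axis
    (Model II) regression of log swimmer density on log resident density or
    biomass with tests of slope = 0 and slope = 1, and standardized swimming
    activity correlations with the variance-to-mean patchiness index. A
    synthetic survey generator reproduces the hierarchical survey design so
    every stage of the pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
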