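Package: crownforge
Title: Crown Width Allometry with Competition and Species Mixed Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling tree crown width in stem-mapped,
    multi-species stands. Reads and validates stem maps, grids a stand into
    plots, computes stand covariates and six plot-level competition indices
    (including distance-dependent Hegyi indices with translation-based edge
    correction), fits and ranks twelve candidate crown-width-diameter
    functions, extends the best form with tree and competition covariates,
    and estimates species-level nonlinear mixed-effects models with
    heteroscedastic variance functions, including an exhaustive
    random-effects structure search. A synthetic stand generator with known
    generative truth supports parameter-recovery testing of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    nlme,
    minpack.lm,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
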