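Package: climdecomp
Title: Climate-Decomposition Species Distribution Models for Abundance Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes gridded breeding-season climate into spatial,
    temporal, and residual (spatiotemporal) components and uses all three as
    covariates in zero-inflated and overdispersed count mixed models of
    survey-route bird abundance. Fits Poisson, negative binomial, ZIP and
    ZINB models with a route random intercept by adaptive Gauss-Hermite
    quadrature, selects the error family and climate-component blocks by
    AIC, isolates the effect of each climate component with prediction
    grids, compares components by rank correlation to classify species as
    responding consistently, oppositely, or not at all to spatial versus
    temporal climate variation, and simulates fast, slow and mixed species
    responses to assess when space-for-time substitution yields valid
    forecasts. A synthetic-data generator emulating unbalanced multi-country
    breeding-bird survey panels and gridded climate makes the full pipeline
    testable without external data.
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
    withr,
    ape,
    glmmTMB,
    yaml
Config/testthat/edition: 3
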