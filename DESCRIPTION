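Package: echogam
Title: Hydroacoustic Echo Integration and Zero-Inflated GAM Ensembles for
    Diel Fish Distribution
Version: 0.1.0
Authors@R:
    person("Mara", "Holmgren", email = "mara.holmgren@lakefish.dev",
           role = c("aut", "cre"))
Description: Tools for studying diel fish distribution in deep oligotrophic
    lakes from split- and single-beam hydroacoustic transect surveys. The
    package generates fully synthetic two-day surveys with known response
    functions (diel vertical migration of zooplankton backscatter, sparse
    large-predator targets, zero-inflated prey counts), filters and
    integrates echoes into 10 m x 100 m cells (blanking zones, target
    strength thresholds, mean volume backscattering strength, a predation
    risk index), fits an ensemble of four generalized additive models
    (quasi-Poisson, negative binomial, binomial, and Gaussian on presence
    rows) with k = 3 smooths and forward selection by GCV/UBRE plus
    likelihood-ratio tests, and provides residual autocorrelation
    diagnostics (Moran's I, Mantel test), day-1-fit/day-2-predict
    validation metrics, diel trade-off summaries, and permutation-based
    threshold detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
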