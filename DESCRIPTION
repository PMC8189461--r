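Package: sealcount
Title: Harbor Seal Stock Abundance from Aerial Line-Transect Surveys
    with Availability Corrections
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates in-water density and total stock abundance of harbor
    seals (Phoca vitulina richardii) from aerial line-transect surveys.
    Fits conventional and multiple-covariate distance-sampling detection
    functions (half-normal and hazard-rate keys with series adjustments,
    Beaufort sea state on the scale parameter), selects models by AIC, and
    applies size-bias correction to expected group size.  Converts seal-borne
    wet/dry and dive-summary tag records into haul-out and dive probabilities
    with Bernoulli and Beta generalized linear mixed models (crossed animal
    and animal-by-week random effects), propagates their uncertainty by Monte
    Carlo simulation, and turns predicted availability into seasonal g(0)
    correction factors.  Combines encounter rates (O2 successive-difference
    variance), detection fits, group sizes and correction factors into
    stratum-season estimates with lognormal confidence intervals, then
    aggregates to management stocks and year-round averages.  Includes a
    synthetic survey and tag-data generator with known truth for calibration
    and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    jsonlite,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
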