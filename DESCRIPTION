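Package: mrdsurvey
Title: Mark-Recapture Distance Sampling for Aerial Wildlife Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Abundance estimation for stratified line-transect aerial surveys
    with two independent observer teams (mark-recapture distance sampling).
    Provides the double-observer conditional logistic detection submodel with
    a nine-model covariate candidate set, conventional distance-sampling
    detection functions (uniform, half-normal, hazard-rate keys with cosine,
    polynomial and Hermite adjustments), AICc/AIC ranking with Akaike-weight
    model averaging including model-selection variance, stratified
    Horvitz-Thompson abundance with a full variance decomposition (detection,
    encounter-rate via systematic paired-transect estimation, and cluster
    size), lognormal confidence intervals, density extrapolation, and a
    synthetic survey generator with known truth for parameter-recovery
    studies. Motivated by on-ice helicopter surveys of polar bears in the
    Kane Basin region, whose published summary tables ship as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
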