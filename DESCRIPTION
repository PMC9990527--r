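Package: rslds
Title: Recurrent Switching Linear Dynamical Systems for Neural Population Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits recurrent switching linear dynamical system (rSLDS) models to
    continuous neural population recordings (e.g. calcium-imaging dF/F traces)
    with behavioral covariates, and characterizes the fitted dynamics:
    per-state eigenvalue time constants, a line-attractor score, latent flow
    fields, slow points and dynamic-velocity landscapes, behavior decoding
    from the slow "integration" dimension with bout-shuffle nulls, rotation
    angle and sequentiality analyses, and single-neuron tuning rasters. A
    synthetic-session generator with known ground-truth eigenstructure
    (line-attractor, rotational, and point-attractor regimes) makes the whole
    pipeline testable end to end without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
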