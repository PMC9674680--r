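Package: h2axdose
Title: Bayesian Radiation Dose Estimation from gamma-H2AX Foci Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calibrates Poisson mixture models whose component means are
    parametric surfaces in absorbed radiation dose and post-exposure time,
    using per-cell gamma-H2AX foci counts from irradiated blood samples.
    The posterior of the calibration coefficients is approximated by
    Laplace's method; the calibration line at any fixed time is obtained by
    the multivariate delta method. Absorbed dose for a newly exposed
    individual is then estimated from aggregate foci data under a prior on
    the unknown time since exposure, either by Monte-Carlo simulation or by
    numerical integration of the exact ratio-of-correlated-normals density,
    yielding posterior means, medians and credible intervals.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
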