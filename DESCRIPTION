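Package: dualgate
Title: Dual-Gated Cardiac PET Simulation, Gating and Respiratory Motion Correction
Version: 0.1.0
Authors@R:
    person("dualgate", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dual-gated (respiratory x cardiac) cardiac PET studies:
    a 4D cardiac-torso phantom with known motion and Poisson counting noise,
    amplitude-based respiratory gating and fixed-time ECG gating into 25
    dual-gates with dwell-fraction bookkeeping, a 2D attenuated parallel-beam
    projector with OSEM reconstruction and CINE-averaged versus phase-matched
    attenuation maps, demons-type non-rigid registration of diastolic
    respiratory gates to the end-expiratory end-diastolic reference, and
    image-quality metrics (SUV, contrast ratio, SNR, CV, CNR, myocardial wall
    thickness as profile FWHM).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
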