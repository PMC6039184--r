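Package: adacode
Title: Adaptive Neural Coding for Dynamic Bayesian Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a Bayesian observer tracking a two-state switching
    Gaussian environment through stimuli transformed by resource-constrained
    adaptive encoders: discretization into a limited set of response levels
    (Lloyd-optimized under inference or reconstruction distortion), two-tap
    temporal filtering under an entropy penalty, and surprise-gated stimulus
    selection. Provides the closed-loop encoder-observer simulation, the
    stationary surprise/uncertainty impact maps for generalized Gaussian
    stimulus distributions, and the diagnostic battery (coding cost, inference
    error, speed/accuracy of inference, entropy-coded spike rasters, metamer
    probabilities, and robustness to transmission noise).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
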