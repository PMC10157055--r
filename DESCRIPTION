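Package: stdpgcn
Title: Sleep Staging with Spike-Timing-Dependent Plasticity Graph Learning
    and Spatio-Temporal Graph Convolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Unsupervised learning of per-epoch channel-connectivity graphs
    from multichannel physiological recordings (polysomnography-like
    signals), and a spatio-temporal graph-convolutional sleep-stage
    classifier with optional domain-adversarial training. Continuous
    signals are converted to spike trains with Ben's Spiking Algorithm
    (FIR-filter based encoding), directed channel connectivity is learned
    per 30-second epoch with a trace-based spike-timing-dependent
    plasticity rule, and stage classification (Wake/N1/N2/N3/REM) combines
    a spectral graph convolution over channels with a temporal convolution
    over neighbouring epochs. A gradient-reversal domain discriminator
    reduces subject-level distribution shift. Includes a synthetic
    polysomnography generator with known ground-truth connectivity, a
    minimal EDF reader, subject-independent cross-validation, and staging
    metrics, so the full pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
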