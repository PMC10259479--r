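Package: decodetime
Title: Minimal Decoding Times for Neural Populations with Periodic Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying the trade-off between decoding speed and
    accuracy in neural population codes built from circular tuning curves.
    Constructs modular populations of single-peaked and periodic (grid-cell
    like) tuning curves with Poisson spiking, decodes stimuli by maximum
    likelihood, computes analytic and Monte-Carlo Fisher-information
    benchmarks, estimates the minimal decoding time needed to suppress
    catastrophic estimation errors, provides closed-form two-module and
    multi-module scaling theory for that time, and simulates a two-layer
    leaky integrate-and-fire readout network tracking time-varying stimuli.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
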