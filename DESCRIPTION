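Package: evastream
Title: Evidence-Accumulation Modelling of Bistable Auditory Streaming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulator and analysis suite for an evidence-accumulation (EVA)
    model of bistable perception in auditory triplet streaming. A three-layer
    stochastic network converts Poisson spike counts of A1-like units into
    binary sampler votes and drives two saturating accumulators whose
    threshold crossings generate perceptual switches. Includes the
    duration-statistics toolkit (normalization, gamma maximum likelihood,
    bootstrap goodness of fit, buildup functions with bootstrap confidence
    intervals), two-parameter response-diagram sweeps, and the classical
    per-triplet signal-detection baseline for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
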