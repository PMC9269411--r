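Package: lateralflow
Title: Center-Surround Apparent-Motion Integration Analysis for V1
    Intracellular Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to design cardinal and radial apparent-motion Gabor
    stimulus protocols around a cell's receptive field, to simulate
    trial-resolved membrane potential and spiking under a
    horizontal-propagation working hypothesis (linearly increasing lateral
    onset latency, exponentially decaying lateral amplitude, optional gated
    supra-linear interaction), and to analyse intracellular recordings:
    spike removal and trace conditioning, peristimulus waveforms and
    histograms, pointwise permutation significance envelopes, thresholded
    response integrals, latency and gain modulation measures, surround
    linear predictors and non-linearity detection, latency-basin regression
    of the apparent speed of horizontal propagation, bilinear phase
    regression, population normalisation and realignment, and speed-tuning
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
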