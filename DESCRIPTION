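Package: spikemg
Title: Spiking Neural Network Feature Extraction for Surface EMG Gesture
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hybrid spiking/formal neural network pipeline for multichannel
    surface electromyography (sEMG) gesture recognition. A layer of
    Izhikevich regular-spiking neurons, one per electrode channel, driven by
    rectified and scaled sEMG and coupled by mutual lateral inhibition, emits
    Tsodyks-Markram short-term-plasticity synaptic outputs that serve as
    low-rate features for a backpropagation-trained sigmoid multilayer
    perceptron classifier. A sliding-window root-mean-square extractor with
    the same window geometry provides the classical baseline, and a
    gesture-structured synthetic sEMG generator supplies reproducible
    recordings at 400 Hz or 2000 Hz so the full pipeline - simulation,
    feature extraction, training, streaming classification and paired
    evaluation - runs end to end without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
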