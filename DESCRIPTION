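Package: ecogstate
Title: Consciousness-Level Estimation from Multichannel ECoG by Soft-Clustered Signal Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates a continuous consciousness level from long multichannel
    electrocorticography (ECoG) or EEG recordings. The signal is band-pass
    filtered, screened for high-amplitude channels, and cut into overlapping
    short windows; seven features are computed per window (relative theta and
    beta band power, 95% spectral edge frequency, Poincare-plot ellipsoid
    radius ratio, Lempel-Ziv complexity, theta-band imaginary coherency, and
    weighted symbolic mutual information), averaged across channels,
    normalised, and soft-clustered with fuzzy c-means and a Gaussian mixture
    model. The average of the two membership traces to the "conscious"
    cluster is the consciousness-level estimate. A seeded synthetic-ECoG
    generator with a planted conscious/unconscious schedule supports
    development and validation without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    mclust,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
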