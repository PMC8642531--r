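Package: steertrf
Title: Anticipatory Decoding of Continuous Steering Actions from EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for detecting and quantifying anticipatory neural encoding
    of a continuous steering action in multichannel EEG. Implements forward
    (encoding) and backward (decoding) lagged ridge regression with
    cross-validated regularisation, temporal response function estimation,
    reversible canonical-correlation-based removal of motion, muscular and
    ocular artifact components, shuffled-fold permutation null baselines, and
    a repeated-measures statistical battery. Includes a synthetic
    driving-session generator with known ground-truth kernels so that the
    whole pipeline can be exercised end-to-end against recoverable truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
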