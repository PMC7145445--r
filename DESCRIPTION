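Package: babynirs
Title: Infant fNIRS Preprocessing, Peak Statistics, and Multivariate Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of infant functional near-infrared
    spectroscopy (fNIRS) language experiments: channel quality control on
    dual-wavelength optical intensity (coefficient of variation and
    normalized spectral peak power), zero-phase low-pass filtering,
    24-second block segmentation with anchored linear detrending, conversion
    of attenuation changes to oxy- and deoxyhemoglobin concentrations via
    the modified Beer-Lambert law, amplitude- and looking-time-based trial
    rejection, peak extraction in the 8-16 s post-onset window,
    channel-wise t tests with Benjamini-Hochberg correction and a
    hemodynamic-consistency rule, region-of-interest mixed-design ANOVAs,
    and leave-one-participant-out linear support-vector-machine decoding
    with participant-preserving permutation inference. A synthetic cohort
    generator with known hemodynamic ground truth makes every stage
    testable without access to infant recordings.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
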