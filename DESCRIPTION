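Package: painhfa
Title: Intracranial High-Frequency Activity Analysis of Tonic Pain Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating broadband high-frequency activity (HFA, 70-150 Hz)
    in stereo-EEG local field potentials to psychophysical pain reports during a
    tonic thermal stimulation task. Provides common-median referencing, epoching,
    threshold- and MAD-based artifact rejection, filter-Hilbert envelope
    extraction with baseline z-scoring, sliding-window generalized linear
    mixed-effects models of binary and graded (visual analog scale) pain reports,
    and a permutation pseudo-t significance procedure. A synthetic-data module
    simulates the adaptive (QUEST-style) psychophysical task, region-resolved
    neural recordings with known injected effect sizes, and the artifact classes
    targeted by the rejection rules, so the full pipeline can be exercised and
    calibrated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    signal,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
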