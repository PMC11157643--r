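Package: fabprofiler
Title: Clonal Fab Repertoire Profiling from Intact-Mass LC-MS Runs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts MS1-only LC-MS runs of intact antibody Fab fragments
    (~46-51 kDa) into clonal repertoire profiles. Implements sliding-window
    spectrum averaging, baseline subtraction and Gaussian smoothing,
    charge-state deconvolution to zero-charge mass spectra by multiplicative
    (Richardson-Lucy-type) updates under an electrospray charge-envelope
    forward model, centroided mass-peak picking, and ppm-tolerance merging of
    per-slice peaks into clone lists (unique mass, retention time, intensity).
    Repertoires are compared with tolerance-matched cosine similarity. A
    synthetic-run generator renders denatured-Fab electrospray runs with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    mzR,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
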