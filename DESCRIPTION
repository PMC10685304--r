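Package: filmqa
Title: Film-Based Dosimetric Quality Assurance for Multi-Fraction
    Online-Adaptive Radiotherapy
Version: 0.1.0
Authors@R:
    person("Film QA", "Maintainers", email = "filmqa@example.org",
           role = c("aut", "cre"))
Description: Tools for patient-specific quality assurance of multi-fraction
    online-adapted MR-linac treatments measured with radiochromic film.
    Implements film calibration with daily rescaling, rigid pin-landmark
    registration of scans, extraction of the film-plane dose from 3D
    calculated dose grids, fraction summation, relative normalization,
    bounded shift correction, global gamma analysis, dose-deviation and
    distance-to-agreement maps, and ionization-chamber point comparisons.
    A synthetic phantom and treatment simulator generates complete
    five-fraction datasets (calculated grids, accumulated film scans, daily
    calibration films, chamber readings) with a known ground-truth ledger so
    the full analysis chain can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
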