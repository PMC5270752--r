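Package: raceSCRS
Title: Single-Cell Raman Spectrum Phenotyping and Raman-Activated Cell
    Ejection Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phenotyping bacterial cells from single-cell Raman
    spectra (SCRS) and planning Raman-activated cell ejection (RACE) sorts.
    Provides a seeded synthetic-cohort generator emulating a marine
    surface-water community, asymmetric-least-squares baseline correction
    with robust noise estimation, fluorescence screening, prominence-based
    peak detection, carotenoid (v1/v2/v3 resonance bands) and
    polyhydroxybutyrate biomarker-band classification, carotenoid typing
    from band-position triplets, principal component analysis with
    loading-window interpretation, and sort-plan/manifest simulation for a
    12-well RACE chip with control wells.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
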