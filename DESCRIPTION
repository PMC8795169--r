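Package: qlineal
Title: Microdosimetric Quality Functions from Lineal-Energy Spectra and
    Tumor Dose-Response Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the microdosimetric characterization of radiation
    quality. Represents single-event lineal-energy spectra f(y) and d(y),
    including a triangular chord-length surrogate generator for ion beams;
    fits a targeted-plus-non-targeted (TE+NTE) tumor dose-response model to
    per-mouse tumor counts by constrained Poisson maximum likelihood with
    profile-likelihood or bootstrap confidence intervals; derives low-dose
    relative biological effect metrics; unfolds parametric biological
    weighting functions q(y) from effect metrics and dose-weighted spectra
    by confidence-interval-weighted multistart least squares; and folds
    fitted weighting functions with arbitrary environment spectra to
    produce effect metrics, mean quality factors, and dose equivalents.
    Includes seed-deterministic synthetic-data generators for every
    pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
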