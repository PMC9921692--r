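Package: sportsimca
Title: Multiblock SPORT-LDA and SIMCA Class Modeling for Infrared Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Chemometric classification workflow for ATR-FT-IR spectral
    fingerprints: ensemble spectral preprocessing (mean centering, standard
    normal variate, Savitzky-Golay derivatives), sequential preprocessing
    through orthogonalization with linear discriminant analysis (SPORT-LDA),
    soft independent modeling of class analogy (SIMCA), principal component
    diagnostics (Hotelling T2 and Q residuals), variable importance in
    projection (VIP) ranking, Duplex calibration/test splitting, and a
    class-structured synthetic spectra generator emulating four celery
    ecotypes for end-to-end verification.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    signal,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
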