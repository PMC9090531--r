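Package: nirsimca
Title: One-Class SIMCA Authentication of Medicine Brands from Handheld NIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric screening pipeline for detecting falsified tablets
    from handheld near-infrared (900-1700 nm) spectra. Provides a synthetic
    spectrum generator emulating a multi-brand antimalarial sampling design,
    spectral preprocessing (wavelength cropping, Savitzky-Golay derivative
    filtering, multiplicative scatter correction), mean-centered PCA with
    Hotelling T2 and Q residual statistics, classical SIMCA one-class brand
    models with Jackson-Mudholkar and F-distribution confidence limits and a
    membership-probability rule, data-driven SIMCA (scaled chi-squared score
    and orthogonal distances with a total-distance acceptance region),
    Kennard-Stone and batch-wise train/test splitting, venetian-blinds
    cross-validation for component selection, and sensitivity/specificity
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
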