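Package: ftirorigin
Title: Geographical Origin Discrimination from Second-Derivative FT-IR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric workflow for authenticating the geographical origin of
    red pepper (Capsicum annuum) powders from attenuated-total-reflectance
    FT-IR spectra. Provides Savitzky-Golay second-derivative preprocessing,
    peak-variable extraction with reference-band normalization, statistical
    screening of peak variables (variance-homogeneity and one-way ANOVA with
    per-variable Wilks' lambda), canonical discriminant analysis with
    leave-one-out cross-validation, and a sequential indicator-range
    classifier, together with a synthetic spectrum and peak-table generator
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    car,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
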