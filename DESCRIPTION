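Package: rfseries
Title: Ultrasound RF Time-Series Tissue Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, input/output, feature extraction and group
    comparison for ultrasound radio-frequency (RF) time-series tissue
    characterization. Builds per-pixel RF time series over a region of
    interest from a sequence of raw RF frames, extracts fourteen
    characteristic parameters (Higuchi and structure-function fractal
    dimensions; spectral slope, intercept, midband fit and four band
    energies; fuzzy entropy, kurtosis, peak amplitude and zero-crossing
    statistics), and compares feature tables between tissue groups with
    two-sample t-tests and one-way ANOVA. Includes an exact fractional
    Gaussian noise generator (circulant embedding) and a seeded cohort
    simulator so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
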