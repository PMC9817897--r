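Package: dabscore
Title: Digital Immunoreactive Scoring of DAB-Stained Tissue Microarray Cores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies diaminobenzidine (DAB) immunostaining in brightfield
    images of tissue microarray cores. Implements Beer-Lambert colour
    deconvolution with the Ruifrok-Johnston H-DAB stain basis, the ImageJ
    "Minimum" and "Default" (legacy IsoData) histogram auto-thresholds, and
    the per-core immunoreactive score (IRS): the percent area of DAB-positive
    tissue multiplied by the histogram-weighted DAB intensity (DABwt%).
    Includes the downstream statistics used to compare scores between
    histological groups (heteroscedastic group contrasts with
    Welch-Satterthwaite degrees of freedom, date-blocked linear models with
    estimated marginal means, a negative-binomial GLM for fluorescence
    intensities, loading-control normalisation and fold-change tests) and a
    synthetic H-DAB core-image generator with known ground truth so the whole
    pipeline is testable without patient material.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    emmeans,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
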