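Package: spotmap
Title: Probabilistic Spatial Mapping of Metabolites in Mass Spectrometry Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms centroided mass spectrometry imaging (MSI) data into
    marked spatial point patterns using data-dependent Gaussian mass-window
    weighting, with the weighting width derived from a LOESS model of peak
    full-width-at-half-maximum (FWHM) versus m/z fitted on a profile spectrum.
    Provides molecular probabilistic maps (MPM): kernel density estimation of
    intensity-weighted point patterns tested pixel-wise against a complete
    spatial randomness (CSR) null model with Benjamini-Hochberg correction,
    yielding hotspot and coldspot contours of significant relative spatial
    abundance or deficiency. Also implements cross-tissue comparisons (CT-MPM),
    collective projections of metabolite ensembles (CPPM), spatial arithmetic
    expressions such as the adenylate energy charge, reading and writing of
    processed imzML, METASPACE annotation import, peak occurrence filtering,
    iterative bisecting peak binning, TIC/RMS normalization, and a synthetic
    ground-truth and noise-injection suite for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    xml2,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
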