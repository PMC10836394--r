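Package: relmeta
Title: Toolkit for RELION Cryo-EM Metadata: STAR I/O, Ice Scoring,
    Pipeline Graphs and Run Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Headless tools for inspecting and filtering the metadata of a
    RELION single-particle cryo-EM project. Provides a lossless STAR-format
    parser and writer exposing loop tables as data frames; a power-spectrum
    ice-quality score computed either natively from MRC micrographs or from
    CTFFIND4 radially averaged profile files; threshold and polygon (lasso)
    selection over metadata tables with STAR re-export; the project job graph
    parsed from pipeline.star; per-iteration tracking of classification and
    refinement runs (convergence series, class distributions, model spectra,
    FSC resolution, angular histograms, processing backlog); normalized 8-bit
    PNG previews of micrographs and CTF images; a deterministic synthetic
    project generator for end-to-end testing; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
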