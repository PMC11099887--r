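Package: lipidccs
Title: Internal Collision Cross Section Quality Control for Ion Mobility Lipidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control and correction of collision cross section (CCS)
    values in ion mobility-mass spectrometry lipidomics by internal
    standardization with uniformly 13C-labeled lipids. Provides a curated
    drift-tube nitrogen CCS reference-library data model with a four-criterion
    curation pipeline and equivalent-carbon-number trend validation, matching
    of measured CCS values against the reference library with signed and
    absolute percent-bias summaries, and lipid class- and adduct-specific
    ensembles of linear CCS correction functions fitted by ordinary least
    squares on combinatorially sampled subsets of 3-6 labeled internal
    standards. A synthetic-data generator with known ground truth and a
    command-line workflow tie the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
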