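Package: ependymap
Title: Marker Gating and Cell-Type Composition of the Ependymal Surface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the cell-subtype composition of the
    adult mouse forebrain ependymal surface from marker expression. Provides a
    calibrated synthetic single-cell count generator with planted subtype
    ground truth, mRNA-dropout thinning and FACS-fraction emulation; the
    standard cell and gene quality-control filters; serial-depletion marker
    gating into ependymal subpopulations with co-expression tables; layered
    immunostaining (z-stack) quantification with the Added, Merged and
    averaged estimators; and inclusion-exclusion reconstitution of the full
    CD133-stratified composition partition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
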