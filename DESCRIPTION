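Package: pepscreen
Title: Screening of Bioactive Peptides from Olive Oil Peptidomics Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end screening chain for endogenous food peptides
    identified by mass-spectrometry peptidomics, from identification
    reports to a ranked shortlist of candidate bioactive peptides.
    Implements peptide sequence parsing with inline modification
    notation, monoisotopic mass and m/z arithmetic, acceptance
    filtering of database-search and de-novo identification reports,
    label-free protein roll-up, bioactive-motif scanning with
    BIOPEP-style frequency (A) and potency (B) scores, simulated
    gastrointestinal digestion under configurable protease
    specificities, multi-criterion candidate selection, and the
    calculators used to confirm activity in vitro: ACE-inhibition
    percent and IC50 from fluorescence plates, and ABTS/TEAC from
    Trolox calibration curves. A synthetic-data module generates
    ground-truthed identification reports and assay plates for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
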