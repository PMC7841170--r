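Package: paleodairy
Title: Authentication of Milk Proteins in Ancient Dental Calculus
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for palaeoproteomic dietary analysis of ancient
    dental calculus. Screens per-sample peptide-spectrum-match (PSM) tables
    against an oral signature reference to authenticate preservation, applies
    engine-specific false-discovery-rate filters, calls dairy consumption per
    individual with a multi-criterion evidence rule, and assigns milk peptides
    to taxa with deamidation-aware matching against a beta-lactoglobulin and
    casein reference panel. Includes preservation quality metrics (cleavage
    specificity, deamidation rates), ZooMS peptide-mass-fingerprint matching
    for fragmentary bone, stable-isotope delta calculations with
    standard-based calibration, and a synthetic-data generator so the whole
    pipeline is exercisable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
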