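Package: pickedgroupfdr
Title: Picked Protein Group FDR Estimation for Shotgun Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Protein group-level false discovery rate (FDR) estimation for
    bottom-up proteomics that stays calibrated on very large, merged datasets.
    Implements protein grouping (none, subset, rescued subset), shared-peptide
    handling (discard, Occam's razor), protein-group scoring from peptide
    posterior error probabilities, and target-decoy competition strategies
    (classic, picked, picked group), together with q-value estimation.
    Also provides an entrapment-database builder based on peptide-level
    shuffling with a controlled shared-peptide fraction, a multi-experiment
    peptide-evidence simulator, and calibration diagnostics comparing reported
    decoy-based FDR against entrapment or ground-truth FDR.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
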