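Package: kinprof
Title: Kinome-Wide Bioactivity Profiling with Alignment-Encoded Kinases
    and Conformer-Ensemble Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Proteochemometric toolkit for kinase-ligand binding affinity
    regression and kinome selectivity profiling. Kinases are encoded from a
    structure-validated multiple sequence alignment (identifier, active-site,
    or full-alignment one-hot); compounds are described by physicochemical
    properties, structural keys, multi-radius circular fingerprints, and a 3D
    conformer-ensemble pharmacophore signature descriptor. An attention-based
    neural regressor with five-fold consensus training predicts bioactivity on
    the log10(nM) scale, and odds-ratio contingency analysis profiles compound
    selectivity across kinase groups. Includes activity-data curation
    (filtering, unit normalisation, deduplication, strict splits), regression
    and classification metrics, kinome-tree annotation export, and a seeded
    synthetic-data generator for desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    pROC,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
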