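Package: pecgira
Title: Infarct-Related Artery Localization from Paper ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers diagnostic-quality 10-second 12-lead ECG from the
    compressed paper-ECG layout (2.5 seconds per lead plus one 10-second
    rhythm lead) by Takens embedding, Poincare-section beat ensembles and
    Karhunen-Loeve reconstruction; derives the vectorcardiogram (VCG) by an
    inverse-Dower style transform; summarises the VCG trajectory as a random
    walk over the eight Cartesian octants and extracts 161 named octant and
    network-topology features; selects features by principal-component
    contribution and Gini importance, balances classes with borderline-SMOTE,
    and localizes the infarct-related artery (HC, E, LAD, LCX, RCA) with a
    four-level hierarchical classifier mimicking coronary angiography.
    Includes a synthetic dipole-based 12-lead ECG generator and a paper-ECG
    renderer/digitizer so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    quadprog,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
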