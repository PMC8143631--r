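Package: degronScreen
Title: Chemical-Proteomics Screening for APC/C Substrates with Degron
    Motif Filtering
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tandem-mass-tag (TMT) chemical-proteomics screens
    for substrates of the anaphase-promoting complex/cyclosome (APC/C).
    Implements reporter signal-to-noise quantification (column
    normalization, summed-S/N filtering, scaling to relative abundances),
    protein inference by picked target-decoy FDR and maximum-parsimony
    set cover, replicate differential-abundance statistics with a
    known-substrate-calibrated fold-change threshold and a noncentral-t
    power analysis, D-box/KEN-box degron motif scanning with
    position-weight-matrix similarity, disorder and localization filters,
    Table-style candidate nomination, a knockout-proteome intersection
    rule, and a high-content mitotic-fraction statistic. A synthetic-data
    module generates every input with known ground truth for calibration
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software, CellBiology
RoxygenNote: 7.3.3
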