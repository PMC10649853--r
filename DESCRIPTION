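Package: phenoscreen
Title: Phenotypic Profiling of Compound Dose-Response Screening Panels
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of multiplexed cell-based phenotypic screening panels in
    which compounds are profiled across stimulated primary human cell systems,
    protein biomarker readouts and ascending doses, with all readouts expressed
    as log10 ratios against vehicle controls. Estimates per-readout significance
    envelopes from historical vehicle-control variability, calls single-dose
    biomarker hits, annotates dose-dependent activities from consecutive-dose
    runs, flags cytotoxic and antiproliferative conditions with broad-
    cytotoxicity dose exclusion, determines optimal doses by hit count, and
    computes direction-matched shared activities between compounds. Ships
    transcriptions of the published reference activity tables for pentadecanoic
    acid (C15:0), rapamycin, metformin and acarbose on a 12-system biomarker
    panel, and a synthetic panel generator with ground truth for calibration
    and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Pharmacogenomics, QualityControl
RoxygenNote: 7.3.3
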