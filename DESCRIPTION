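Package: glycoCSC
Title: Cell-Surface Capture Glycoproteomics: Curation, Detectability
    Scoring, Classification and Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for curating cell-surface capture (CSC) N-glycoproteomic
    evidence into a classified surface N-glycoprotein catalog. Implements
    in-silico tryptic digestion with N-glycosylation sequon (SCM) enumeration
    and an m/z-based detectability score over predicted extracellular regions,
    deamidation-in-SCM detection from peptide-spectrum-match tables, master
    protein resolution, capture-specificity reporting, a decision-rule surface
    classifier, transmembrane orientation inference from glycosite parity,
    Gini-dispersion marker prioritization, a label-free quantification
    workflow (equalize-median normalization, Tukey median polish, accelerated
    failure time imputation of left-censored intensities, two-group testing
    with Benjamini-Hochberg correction), exclusive set-intersection
    accounting, and synthetic fixture generators with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
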