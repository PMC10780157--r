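Package: endoSISS
Title: Similarity Scoring of Expert Sulcal Annotations on Brain Endocasts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how accurately and consistently raters identify
    brain sulci drawn on 2D views of an endocast. Per-sulcus binary masks are
    compared against reference sulci with the Dice overlap coefficient and a
    directed mean minimum Euclidean distance (MMED) computed from a
    single-pixel-wide centroid streamline of each drawing; the two are
    combined into the SISS similarity index. Includes the 42-entry sulcus
    nomenclature with its merge rules, a label-correction mechanism that
    separates raw from corrected analyses, per-sulcus/per-view/per-hemisphere
    aggregation with identification rates and reliability-zone
    classification, and a deterministic synthetic cohort generator that
    emulates rater error modes (displacement, smooth deformation, truncation,
    rectilinear bias, omission, mislabelling) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'aggregate.R'
    'cli.R'
    'endoSISS-package.R'
    'labelset.R'
    'masks.R'
    'similarity.R'
    'synthetic.R'
    'utils.R'
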