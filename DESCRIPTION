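Package: milscreen
Title: Weakly Supervised Slide Classification and AI-Assisted Mutation
    Screening Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for attention-based multiple-instance
    learning on whole-slide images and for calibrating AI-assisted
    molecular screening workflows. Provides synthetic slide and cohort
    generators with known statistical structure, tissue detection and
    patch gridding at a stated working resolution, a gated-attention
    aggregator with a linear probability head and a seeded training
    loop, attention-map introspection (z-scored masks, high-attention
    regions, densest-region boxes, overlays), ROC/AUC evaluation with
    bootstrap confidence intervals and subgroup analyses, and a
    dual-threshold triage calibrator (NPV/PPV/test-reduction surfaces,
    noninferiority regions, operating-point selection and deployment
    evaluation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
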