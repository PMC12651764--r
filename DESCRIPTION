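Package: prepscore
Title: Automated Rubric Scoring of 3D Dental Cavity Preparations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for automated, rubric-based scoring of scanned dental
    cavity preparations. Reads triangle meshes in Wavefront OBJ format,
    samples them into deterministic fixed-size point clouds normalized to the
    unit sphere, and scores them with a point-cloud regression network of the
    PointNet family (shared per-point transforms, symmetric max-pooling,
    fully connected head, bounded outputs) trained to minimize mean absolute
    error in rubric points. Ships a 9-item, 20-point restorative-dentistry
    rubric with deduction and pulp-exposure semantics, JSON score labels, a
    parametric generator of synthetic molar-like preparations with known
    ground-truth scores, and a method-agreement suite (MAE, RMSE, Pearson,
    Spearman, Lin's concordance, Bland-Altman, ICC(2,1), within-threshold
    accuracy) for comparing model and examiner scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
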