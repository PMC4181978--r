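Package: fprs
Title: Fuzzy-Set Potential Range Shift Indices for Species Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Threshold-free quantification of projected species range shifts
    from continuous habitat-suitability rasters. Treats a suitability map as a
    fuzzy set whose cell memberships equal the model's logistic output, and
    derives the F-PRS index set: range increment (I), fuzzy range overlap (O),
    and the three-dimensional displacement (Dx, Dy, Dz) of the
    membership-weighted range centroid over a digital elevation model. Includes
    cell-wise median ensemble consensus across GCM x predictor-set member
    models, model evaluation (AUC, maximum kappa and maximum TSS over a
    threshold grid), genus/family-level significance testing (one-sample t
    tests against zero, one-way ANOVA across climate scenarios with gated LSD-t
    pairwise comparisons and compact letter displays), the PRS_Chart circular
    diagram with logarithmically scaled displacement arrows, ESRI ASCII grid
    input/output, a virtual-species generator for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, grDevices, graphics
Suggests: testthat (>= 3.0.0), jsonlite, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'grid-core.R'
    'prs-indices.R'
    'chart.R'
    'model-eval.R'
    'group-stats.R'
    'synthetic.R'
    'io.R'
    'cli.R'
    'ensemble.R'
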