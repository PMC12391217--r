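Package: scapssm
Title: Scapula Shape Reconstruction from Skin Landmarks via Statistical
    Shape Modeling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds principal-component statistical shape models (SSM) of
    the scapula from corresponded triangle meshes and reconstructs
    subject-specific scapula surfaces from four digitized skin landmarks
    (AA, TS, AI, AC) plus demographics. Includes mesh input/output for
    PLY, STL and OBJ with isotropic remeshing; ISB body-fixed scapular
    coordinate frames; rigid and non-rigid registration for dense
    point-to-point correspondence; skin-to-bone landmark regression via
    stepwise selection with F-test entry/removal and fold-scored best
    model choice; penalized landmark fitting solved by a seeded genetic
    algorithm with bounded quasi-Newton refinement; shape-model
    validation metrics (compactness, generalization, specificity);
    reconstruction error metrics (landmark-to-landmark and
    surface-to-surface) with Kruskal-Wallis comparisons; and a synthetic
    scapula-like population generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
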