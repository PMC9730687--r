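Package: recistmask
Title: Automated RECIST 1.1 Treatment-Response Assessment from 3D Lesion Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automated, rule-based tumour treatment-response
    assessment from 3D segmentation masks, as used for liver metastases on
    diffusion-weighted MRI. Reads NIfTI label volumes, extracts connected
    lesion components, measures longest axial (Feret) diameters and volumes,
    and applies the RECIST 1.1 rules (10 mm measurability, up to five target
    lesions, percent change of the diameter sum, count-based new-lesion rule)
    to classify baseline/follow-up pairs as complete response, partial
    response, stable disease or progressive disease. Also provides the
    evaluation machinery used around such pipelines: Dice, volumetric
    similarity and Hausdorff distance for segmentation quality; confusion
    matrices, exact-binomial accuracy intervals, Cohen's kappa and ROC AUC
    for rater agreement; a synthetic phantom generator producing anisotropic
    liver/lesion masks with analytic ground truth; and a compact pure-R
    two-stage (liver then lesion) 3D U-Net for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    pROC,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    yaml
Config/testthat/edition: 3
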