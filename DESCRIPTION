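Package: spinecobb
Title: Automatic Coronal Cobb Angle Measurement from Labeled Spine Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the coronal (and sagittal) Cobb angle of degenerative
    lumbar scoliosis from 3D labeled segmentation volumes of vertebrae and
    intervertebral discs. Each disc mask is converted to a surface mesh,
    split into upper and lower halves by a PCA mid-plane, and a plane is
    fitted through each half; projecting the half-plane normals onto the
    coronal plane yields per-endplate tilt angles, and the maximum absolute
    difference over all endplate pairs is the Cobb angle. Includes quality
    control of segmentations, AP-radiograph-like coronal projection images
    with measurement overlays, a synthetic spine phantom generator with
    analytically known ground truth, and reader-agreement statistics (MAE,
    two-way random-effects ICC with confidence intervals, Bland-Altman
    limits of agreement, consensus levels, and a 5-degree clinical
    acceptance simulation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    png,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
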