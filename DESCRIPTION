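Package: segqa
Title: Quantifying Geometric Variability of Image Segmentation Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for measuring the geometric variation that segmentation
    and mesh-refinement workflows introduce into 3D-printable anatomical
    models. Generates synthetic CT-like phantoms (a mandible arch with an
    adjacent cortex-eroding tumor and thin nerve canals) with ground-truth
    masks and landmarks; segments them with parameterized workflows
    (thresholding, region growing, morphology, slice interpolation);
    extracts watertight triangle surfaces; applies Laplacian and Taubin
    smoothing and quadric decimation; and compares the resulting models
    with global metrics (volume, surface area, voxelized agreement and
    disagreement percentages, signed Hausdorff deviation fields) and local
    metrics (landmark calipers, parallel datum-plane contour slicing,
    nerve-path centroid analysis), with one-way ANOVA and Tukey-Kramer
    post-hoc statistics and reproducible report generation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
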