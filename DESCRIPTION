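Package: cardiomesh
Title: Tagged Anatomical Model and Fiber Generation for Cardiac Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds personalized, tagged, fiber-annotated tetrahedral models
    of biventricular cardiac anatomy from segmented 3D label images. Provides
    tagged label-image I/O (NIfTI, NRRD), synthetic biventricular phantoms
    with analytically known surfaces, multi-material surface extraction with
    exact interface coincidence, constrained variational surface smoothing
    (quadratic Laplacian penalty under per-vertex half-voxel box constraints),
    re-rasterization at arbitrary resolution, conforming tagged tetrahedral
    meshing, boundary-surface derivation by face-set algebra, and
    Laplace-Dirichlet rule-based myocardial fiber assignment, with writers for
    CARP, VTK/VTU and STL formats.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
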