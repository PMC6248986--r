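Package: lcpore3d
Title: Three-Dimensional Morphometry of Lamina Cribrosa Pores from C-Scan Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the three-dimensional structure of lamina cribrosa pores
    from per-C-scan margin-point annotations, as used in swept-source OCT studies
    of the optic nerve head. Margin points are ordered into simple polygons,
    rasterized into an anisotropic voxel solid, and summarized by six morphometric
    parameters: mean cross-sectional area, volume, volume adjusted to lamina
    cribrosa thickness, true sphericity (from a sub-voxel surface mesh), and the
    three principal values of the voxel-coordinate covariance. Includes a
    calibrated synthetic phantom generator emulating annotated normal and glaucoma
    pore cohorts, quartile-based topographic severity maps, and Mann-Whitney U
    group comparisons with exact small-sample p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    tiff,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
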