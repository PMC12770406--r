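Package: cervimetry
Title: Automated Multi-Layer Cervix Segmentation, Biometry and Volumetry for 3D MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for multi-layer analysis of the uterine
    cervix in motion-corrected 3D T2-weighted MRI volumes. Provides a
    five-label parcellation convention (endocervical canal, inner and outer
    stroma, cysts, bladder), landmark-based biometry (two-line cervical
    length, inlet and outlet canal diameters), per-label volumetry with
    cyst merging, evaluation metrics (Dice, volume differences, intraclass
    correlation), a trainable reduced-scale 3D UNet segmentation network,
    groupwise atlas construction with Laplacian sharpening, and
    gestational-age normative chart generation. A parametric cervix phantom
    generator with analytically known geometry makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
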