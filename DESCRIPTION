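Package: spinefe
Title: Voxel Finite-Element Analysis of Vertebral Cement Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based finite-element analysis of vertebroplasty in
    three-vertebra spine segments. Provides a synthetic quantitative-CT
    phantom of a T12-L1-L2 segment, greyscale thresholding and
    greyscale-to-modulus material mapping, a voxel hexahedral linear
    elasticity solver with displacement-controlled loading, inverse
    calibration of intervertebral disc properties against a measured
    segmental stiffness, parametric treatment operators (cement modulus
    and volume, bone quality, disc state, single- and two-level
    augmentation), and element-wise von Mises stress-redistribution
    statistics at a common reaction force.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    RNifti,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
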