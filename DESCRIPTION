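Package: fetalshim
Title: Localized and Fat-Constrained Image-Based B0 Shimming for Fetal EPI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Image-based static B0 shimming for echo-planar imaging of the
    fetal brain. Computes off-resonance field maps from dual-echo gradient-echo
    data, unwraps phase with a Goldstein branch-cut method, separates water and
    fat with a three-point Dixon model, and fits first- and second-order
    spherical-harmonic shim coefficients over a fetal-brain ellipsoid, either
    unconstrained (localized) or with per-voxel inequality constraints that keep
    the residual frequency in maternal fat regions inside the effective band of
    a spectral fat-saturation (SPIR) pulse. The fat-frequency band is derived by
    hard-pulse Bloch simulation of the saturation pulse. A parametric synthetic
    maternal-abdomen phantom generator makes the full pipeline runnable and
    testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    quadprog,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'dixon.R'
    'evaluate.R'
    'fetalshim-package.R'
    'fieldmap.R'
    'geometry.R'
    'io-nifti.R'
    'phantom.R'
    'pipeline.R'
    'shim-model.R'
    'shim-optimize.R'
    'spir.R'
    'unwrap.R'
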