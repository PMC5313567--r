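Package: pbitomo
Title: Reconstruction Workflows for Propagation-Based Phase-Contrast Micro-CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scriptable reconstruction workflows for single-distance
    propagation-based phase-contrast (PBI) synchrotron micro-CT. Provides
    conventional and dynamic (eigen-flat-field) flat fielding, rotation-axis
    estimation and extended field-of-view stitching for 360-degree offset
    ("half acquisition") scans, Fourier-space sinogram de-striping for ring
    artifact compensation, single-distance phase retrieval (Paganin TIE-Hom
    and CTF / projected-CTF), and parallel-beam reconstruction by filtered
    back projection or SIRT with a matched projector pair. A physics-based
    simulator (ellipse phantoms with an analytic Radon oracle, Fresnel
    free-space propagation, detector gain and beam-drift corruption models)
    generates fully controlled synthetic datasets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'core_model.R'
    'utils_fft.R'
    'simulator.R'
    'flat_fielding.R'
    'geometry_ops.R'
    'io_tiff.R'
    'io_formats.R'
    'pbitomo-package.R'
    'ring_removal.R'
    'phase_retrieval.R'
    'reconstruction.R'
    'pipeline.R'
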