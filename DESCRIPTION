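Package: flow4d
Title: Hemodynamic Post-Processing of 4D Flow MRI Velocity Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-processing of time-resolved three-directional
    phase-contrast MRI (4D flow MRI) velocity fields, as used to
    characterise the hemodynamics of pulsatile blood pumps and cardiac
    chambers. Provides background phase-offset correction from a static
    acquisition, magnitude-threshold segmentation, voxel-wise flow
    metrics (kinetic energy, viscous dissipation and energy loss,
    scalar shear stress, turbulent kinetic energy from intravoxel
    velocity variation, relative stasis), integrated summaries (flow
    rate, stroke volume, Reynolds number, regional time series,
    maximum-intensity projections, histograms, quartiles, line
    profiles), and detection of flow-separation (recirculation) zones
    from the zero-axial-velocity isosurface. Analytic flow phantoms
    with closed-form ground truth make the full pipeline testable
    without any acquired data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    igraph
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'flow4d-package.R'
    'io.R'
    'metrics.R'
    'phantoms.R'
    'pipeline.R'
    'preprocess.R'
    'recirculation.R'
    'summaries.R'
    'utils.R'
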