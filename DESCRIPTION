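Package: matnets
Title: Maturational Network Analysis of Developmental Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates resting-state networks from the age-related change in
    voxelwise functional connectivity across a cross-sectional cohort
    ("maturational networks"), rather than from the group-average correlation
    structure. Implements per-subject dense connectomes, streaming age-effect
    regression into a maturational dense connectome, incremental block SVD
    reduction, fixed-point spatial ICA, the reference group-ICA plus
    dual-regression pipeline with mass-univariate age modelling, emerging
    connectivity profiles, the maturational connectome with spectral embedding
    and Ward grouping, maturational hubs, coupling trajectories, univariate
    signal-property diagnostics, and a synthetic-cohort generator with planted
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'accessors.R'
    'assignment.R'
    'connectome.R'
    'migp.R'
    'ica.R'
    'groupica.R'
    'io.R'
    'matnets-package.R'
    'profiles.R'
    'synthetic.R'
    'univariate.R'
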