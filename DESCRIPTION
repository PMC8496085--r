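Package: cardioshape
Title: Biventricular Shape Atlas Analysis of Cardiac Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical shape modelling of corresponded biventricular
    (left and right ventricle) surface meshes at end-diastole and
    end-systole. Provides generalized Procrustes alignment, principal
    component atlases with standardized morphometric scores, per-mode
    regression of shape on clinical covariates with shape-difference
    reconstruction, model-derived remodeling features (basal bulge,
    tricuspid tilt, apical angle, mid-ventricular dimensions), geometric
    systolic strains from arc lengths and centerline wall thickness,
    cavity volume and myocardial mass by mesh integration, and a
    synthetic-cohort generator with planted deformation modes and
    covariate effects for validation without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
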