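Package: octsynth
Title: Synthetic Retinal OCT Volumes from Statistical Shape Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates labeled synthetic optical coherence tomography (OCT)
    data of the macula. A three-dimensional point distribution model (PDM)
    is fitted to landmarked retinal boundary surfaces by generalized
    Procrustes alignment and principal component analysis; new boundary
    geometries are sampled from the model, rendered into intensity volumes
    with per-layer brightness, synthetic vasculature (bright inner / dark
    outer vessel shadows), choroid and background compositing and
    multiplicative speckle noise. An unconstrained two-dimensional variant
    synthesizes diabetic macular edema (DME) B-scans with column-wise
    texture and fluid-mask transfer from a reference library. Includes the
    evaluation battery used to validate such generators: layer thickness
    maps, en-face projection images, gray-level co-occurrence matrix (GLCM)
    texture features, quantile-quantile point sets and two-sample
    Kolmogorov-Smirnov tests, plus a seeded phantom generator so the whole
    pipeline runs without real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tiff,
    RNifti,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
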