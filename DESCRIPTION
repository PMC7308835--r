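Package: hyperFP
Title: Hyperspectral Chemometrics for Free Proline Phenotyping in Rice Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for high-throughput estimation of free proline (FP,
    mg/g fresh weight) in rice leaves under cadmium stress from
    visible/near-infrared hyperspectral images. Provides ENVI-style cube
    input/output with white/dark reflectance calibration, NIR-threshold
    leaf segmentation and mean-spectrum extraction, three calibration
    engines (NIPALS partial least squares, least-squares support vector
    machine with RBF kernel, and extreme learning machine) tuned by
    leave-one-out cross-validation, three wavelength-selection methods
    (competitive adaptive reweighted sampling, a genetic algorithm, and
    PLS regression-coefficient extrema), rank-based calibration/prediction
    splitting, per-wavelength ANOVA profiling, compact letter displays for
    treatment groups, and pixel-wise FP distribution maps. A synthetic
    study generator reproduces the full five-concentration by four-day
    cadmium stress design with known FP ground truth so the complete
    pipeline can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    igraph,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'synth.R'
    'cube_io.R'
    'preprocess.R'
    'chemometrics.R'
    'wavesel.R'
    'evalstats.R'
    'mapping.R'
    'pipeline.R'
    'hyperFP-package.R'
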