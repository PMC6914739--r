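Package: decodeHD
Title: Simulation, Classification and Population Decoding of Head-Direction Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking neural decoders on head-direction (HD)
    cell populations. Simulates heading trajectories and inhomogeneous-Poisson
    HD-cell spike trains with von Mises tuning, classifies HD cells with
    shuffle-based mean-vector-length and stability criteria (plus a
    Rayleigh-test variant for sparsely firing cortical cells), and decodes
    heading from binned population activity with six statistical model-based
    methods: Kalman filter, Poisson generalized linear model with a point
    process filter, vector reconstruction, optimal linear estimator, Wiener
    filter and Wiener cascade. Includes circular error metrics (median and
    mean absolute error after rescaling to [-180, 180] degrees), contiguous
    train/test splits, dataset-level accuracy factors (cell count, tuning
    strength, response rate, angular head velocity) with linear-regression
    and sequential-removal repeated-measures ANOVA analyses, and optional
    machine-learning decoder adapters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    e1071,
    xgboost,
    nnet,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils-circular.R'
    'AllGenerics.R'
    'AllClasses.R'
    'synthetic.R'
    'io.R'
    'binning.R'
    'classify.R'
    'decode-kf.R'
    'decode-glm.R'
    'decode-popvec.R'
    'decode-wiener.R'
    'decode-registry.R'
    'evaluate.R'
    'factors.R'
    'ml.R'
    'cli.R'
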