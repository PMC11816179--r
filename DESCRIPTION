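Package: intervalRT
Title: Interval Analysis-Based Robust IMRT Fluence Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Robust fluence-map optimization for intensity-modulated
    radiotherapy (IMRT) under geometric setup uncertainty, representing
    per-voxel dose as an interval (expected dose, standard-deviation spread)
    built from scenario dose-influence matrices. Implements the Bertoluzza
    interval metric as a clinical target volume objective with a tunable
    robustness weight, singular value decomposition compression of the dose
    variability representation, nominal, margin-based (PTV) and minimax
    comparison models, a desk-scale pencil-beam dose engine on synthetic
    prostate-like voxel phantoms, and a robustness evaluation suite
    (robustness index, Delta-maps, confidence-band dose-volume histograms,
    price-of-robustness metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
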