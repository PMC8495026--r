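Package: sparecg
Title: Symmetric Projection Attractor Reconstruction for ECG Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms quasi-periodic physiological signals into
    two-dimensional "attractor" point clouds via N-point delay-coordinate
    embedding and symmetric projection, and quantifies them with polar
    measure profiles (radial density, angular density, outline radius).
    Includes a Pan-Tompkins style QRS detector to set the delay spacing,
    readers and writers for WFDB and CSV electrocardiogram records, a
    seeded synthetic 12-lead ECG generator with two morphology classes,
    cohort-level profile summaries with centile bands and group-distance
    statistics, conventional corrected-interval metrics, and a stacked
    classifier (per-measure-set k-nearest-neighbour posteriors feeding a
    shallow neural network) with stratified, leakage-audited nested
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    class,
    nnet,
    optparse,
    withr
Config/testthat/edition: 3
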