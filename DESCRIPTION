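Package: gaitfall
Title: Wearable-Sensor Gait Features and Elderly Faller Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying older adults as fallers or non-fallers
    from short-walk wearable-sensor recordings. Generates synthetic
    multi-sensor gait trials (tri-axial accelerometry at four body sites,
    pressure-insole force and centre-of-pressure streams), extracts the
    plantar-pressure feature bank (centre-of-pressure path, temporal, and
    mass-normalised impulse features) and the 29-feature accelerometer bank
    (directional statistics, cadence, FFT first-quartile percentage, ratio
    of even to odd harmonics, maximum Lyapunov exponent), performs filter
    feature selection (correlation-based feature selection, fast
    correlation-based filter, Relief-F with incremental subset sizing),
    trains a classifier bank (single-hidden-layer perceptrons, linear and
    quadratic Gaussian naive Bayes, polynomial-kernel support vector
    machines), and evaluates models with seven performance metrics, Wilson
    score confidence intervals, summed-rank model ranking, and
    repeated-random-sampling stability analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    e1071,
    nnet,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
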