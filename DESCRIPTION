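Package: kwarp
Title: T-Wave Time-Warping Markers for Noninvasive Blood Potassium Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to estimate relative blood potassium variation in
    hemodialysis patients from multi-lead Holter ECG. Implements zero-phase
    Butterworth preprocessing, single-lead QRS detection and T-wave
    delineation, periodic component analysis (a generalized-eigenvalue lead
    transformation maximizing one-beat T-wave periodicity), mean warped
    T-wave computation with square-root-slope-function dynamic-programming
    time warping, the signed and heart-rate-corrected warping markers, and
    per-patient monotonicity-constrained polynomial sensing models with
    all-samples and leave-one-out evaluation. A synthetic Holter-session
    generator with analytic ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
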