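Package: crysig
Title: Acoustic Signatures of Infant Cries: Synthesis, Descriptors, and
    Classification Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying what infant cries encode. Provides a
    parametric source-filter synthesizer for cry-like vocalizations and a
    latent-trait cohort simulator with individual signatures, age drift,
    cause effects and session confounds; amplitude-envelope segmentation of
    crying bouts with a four-condition cry filter (voicing, median pitch,
    duration, Wiener entropy); ten per-cry acoustic descriptors (median
    pitch and pitch IQR, voicing, spectral centroid, Wiener entropy,
    harmonics-to-noise ratio, jitter, shimmer, modulation-spectrum
    roughness, duration); session-grouped stratified random-forest
    experiments for sex, age, identity and cry cause with odds-ratio-to-
    chance summaries, test-retest transfer matrices across age groups,
    per-baby cause models and cross-context distance correlations; and a
    dynamic-time-warping distance over frame-wise acoustic contours with a
    2D embedding and silhouette diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    signal,
    ranger,
    cluster,
    MASS,
    Rcpp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    tidyr,
    withr
LinkingTo:
    Rcpp
NeedsCompilation: yes
Config/testthat/edition: 3
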