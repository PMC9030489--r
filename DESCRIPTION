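Package: swaylab
Title: Accelerometer-Based Assessment of Working Postural Stability
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to quantify the stability of static working postures from
    wearable tri-axial accelerometer (IMU) recordings. Implements a registry of
    43 acceleration-based sway measures (Prieto-style time-, frequency- and
    area-domain statistics plus Raymakers phase-plane parameters) computed per
    sensor and trial, the center-of-pressure reference measure COPV_AP,
    three-way repeated-measures ANOVA with Mauchly sphericity checks and
    Greenhouse-Geisser correction for factor-effect detection, and a
    stable/unstable posture classification grid (sensor configurations x
    feature sets x classifier roster) evaluated by stratified k-fold
    cross-validation. A coupled synthetic-study generator emulates the
    6 posture x 2 surface x 2 load within-subject factorial design so the full
    pipeline is testable without human-subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    MASS,
    rpart,
    randomForest,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
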