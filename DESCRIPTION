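Package: wearimu
Title: Wearable Inertial Sensor Quantification of Parkinsonism and Dystonia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for body-worn inertial measurement units
    (tri-axial accelerometer and gyroscope) recorded while participants
    perform standardized motor tasks and straight walking. Provides
    zero-phase band-limiting, task segmentation and sliding-window
    extraction; time- and frequency-domain window features; shank-mounted
    gait event detection with stride-level temporal and height-normalized
    spatial parameters, cadence, regularity and symmetry; random-forest
    variable-importance feature ranking, Sammon mapping projections,
    cost-sensitive random-forest estimation of ordinal clinical scores
    under grouped (leave-one-subject-out or leave-one-side-out)
    cross-validation, inverse-power-law learning curves, and mixed-effects
    group contrasts; plus a synthetic labeled IMU cohort generator that
    supplies analytic ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    randomForest,
    lme4,
    lmerTest,
    emmeans,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
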