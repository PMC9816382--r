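Package: golfSPI
Title: Swing Performance Index from 3D Golf Swing Kinematics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Swing Performance Index (SPI), a single-score summary
    of golf swing rotational biomechanics derived from 3D marker trajectories.
    Reads motion-capture marker files (TRC and a documented CSV dialect),
    computes transverse-plane pelvis and upper-torso orientations, rotational
    velocities and X-prime (pelvis minus torso velocity), detects swing-phase
    events (backswing start, top, impact, follow-through end), estimates
    clubhead speed at impact via a 3D circle fit, and extracts nine candidate
    rotational metrics per swing. A chosen metric subset is consolidated into
    the SPI by pro-referenced z-scoring, SMOTE class balancing, PCA fitted on
    the professional cohort, and scaling of the log Euclidean distance to the
    average pro swing so that professionals score 100 with standard deviation
    10. Subset selection screens all combinations of up to three metrics by
    the Kaiser-Meyer-Olkin criterion and ranks survivors by leave-one-out
    cross-validated logistic-regression AUC. A seeded synthetic-swing
    generator with known ground truth supports validation end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite,
    signal,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
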