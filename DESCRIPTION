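Package: footspm
Title: Multi-Segment Foot Kinematics, Running Kinetics, and 1D Statistical
    Parametric Mapping for Stance-Phase Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for the secondary-outcome
    analysis of two-arm pre/post running trials: synthetic cohort generation
    with plantable group-by-time effects (ground reaction force waveforms and
    multi-segment foot poses), zero-lag Butterworth filtering, 30 N stance
    event detection, 101-node stance normalization, Joint Coordinate System
    angle decomposition for the shank-calcaneus-midfoot-metatarsus-hallux
    chain plus planar arch and metatarsal angles, extraction of six discrete
    injury-risk parameters (medial longitudinal arch range of motion, rearfoot
    frontal peaks, vertical impact peak, vertical average loading rate, peak
    braking force), linear mixed-model group-by-time inference with
    Bonferroni-adjusted estimated marginal means and Cohen's d, and
    one-dimensional statistical parametric mapping (t, F and Hotelling T2
    fields) with random-field-theory critical thresholds, suprathreshold
    clusters, Sidak-corrected post hocs, and a permutation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
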