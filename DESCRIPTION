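Package: mazeremap
Title: Cue- and Reward-Driven Spatial Remapping Analyses for Tree-Maze and
    Open-Field Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for parahippocampal single-unit recordings
    during a cued goal-directed Tree-Maze task and open-field foraging.
    Provides trial parsing from behavioral event logs, trial-wise 39-zone
    firing-rate maps with balanced bootstrap resampling, condition-dependent
    remapping scores (Kendall correlations compared through Fisher z),
    Mann-Whitney UZ segment statistics, linear zone encoding models with
    additive and interactive cue terms, multinomial position and decision
    decoders, open-field speed/head-direction/position tuning metrics and
    encoding models with functional clustering, across-session unit matching
    from spike-waveform clouds, and a synthetic-session generator with known
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    glmnet,
    lme4,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    mclust,
    kernlab,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
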