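Package: exerstep
Title: Movement Characteristics from Step-Based Balance Exergames
Version: 0.1.0
Authors@R: person("exerstep", "developers", email = "exerstep@users.noreply.github.com",
    role = c("aut", "cre"))
Description: Measurement and analysis chain for step-based balance-training
    exergames played by older adults. Reads 22-marker optical motion-capture
    trajectories (tab-separated exports or C3D), detects lateral steps,
    single-leg support and arm lifts with velocity-threshold segmentation,
    computes per-trial movement characteristics (step size, cadence,
    single-support duration and ratio, arm-lift frequency, sternum occupancy
    heatmaps, anterior drift), scores structured game event logs, and fits
    linear mixed-effects models of game speed, obstacles, repetition, gender
    and body side. Ships a full synthetic exergame-player simulator with
    ground-truth event annotations for validation and parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
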