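Package: plantimp
Title: Swept-Frequency Plant Bioimpedance Simulation and Light-State
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a plant-to-machine bioimpedance sensing chain --
    a square-wave-excited RLC band-pass front end loaded by a Cole-model
    plant impedance with an envelope detector -- and generates labeled
    per-minute bursts of amplitude sweeps under irregular light/dark
    schedules with lagged plant response, baseline drift and measurement
    noise. Provides the burst payload encoding and an on-disk dataset
    container, transition filtering, chronological splitting and
    train-fit standardization, an LSTM classifier with additive
    attention trained by Adam with early stopping and learning-rate
    plateau reduction (including cross-plant fine-tuning), integrated
    gradients attribution with per-frequency importance summaries, and
    per-cycle accuracy and detection-delay evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
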