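Package: optokin
Title: Kinematics of Optogenetically Evoked Eye Movements and Cerebellar
    Spike-Train Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for analyzing optogenetically evoked
    and sensory-driven eye movements together with the accompanying
    spike-train measurements. Provides calibrated angular eye traces,
    zero-phase velocity profiles with quick-phase (saccade) removal,
    per-cycle quality control, four-phase kinematic decomposition
    (drive, hold, release, recovery) with per-phase linear-fit velocity
    and area-under-the-curve distance, pointwise between-group t-score
    divergence maps, peri-stimulus firing-rate modulation with 5-ms
    PSTHs, the CV2 interspike-interval regularity statistic,
    current-step input-output curves, and cycle-folded analysis of
    vestibulo-ocular and optokinetic reflex paradigms with condition
    subtraction. A synthetic-data module generates eye traces and
    gamma-renewal spike trains with closed-form ground truth so every
    stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
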