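Package: reflexgait
Title: Muscle-Spindle Reflex Feedback in Forward Gait Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward simulation of sagittal-plane gait with a muscle-spindle
    stretch-reflex feedback layer. Muscle length and lengthening-velocity
    feedback pathways with gait-phase reflex modulation are layered on a
    muscle-driven planar skeleton with elastic-foundation foot-ground
    contact, so that the effect of hyperexcitable feedback gains and
    stroke-type modulation patterns on joint kinematics can be simulated
    and summarized per gait phase. Includes H-reflex style processing of
    stimulus-locked recordings into modulation curves, a segmented
    open-loop simulation protocol with per-phase effect summaries, a
    synthetic gait-data generator, and readers and writers for columnar
    motion time-series files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
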