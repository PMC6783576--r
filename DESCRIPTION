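Package: chirpjar
Title: Chirps, Tumultuous Rises and Jamming Interactions in Pulse-Type
    Electric Fish Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for electromotor behavior of pulse-type
    weakly electric fish (gymnotiforms) recorded during conspecific
    playback. Detects electric organ discharges (EODs) after digital
    subtraction of the playback stimulus artifact, builds inter-pulse
    interval series, and extracts chirps (abrupt interval reductions),
    burst-like chirping, tumultuous rises and EOD interruptions by
    explicit interval-based rules. Quantifies dyadic phase interactions
    with a sliding-window jamming index tested against a permutation
    null, plus circular statistics (Rayleigh test) of chirp timing. A
    ground-truthed synthetic-trial generator emulates the statistical
    structure of playback experiments so every stage is testable without
    animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
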