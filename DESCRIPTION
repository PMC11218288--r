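Package: fuzzydda
Title: Fuzzy Dynamic Difficulty Adjustment Engine for Upper-Limb
    Rehabilitation Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A computational engine for adaptive serious games used in
    upper-limb motor rehabilitation. Maps therapist-entered clinical
    evaluations (manual muscle testing grades, active joint range of
    motion, Brunnstrom stage, pain score) to initial game difficulty
    through fuzzy inference, adjusts difficulty online with a two-stage
    controller (a crisp Yerkes-Dodson hit-rate gate wrapping a Mamdani
    fuzzy magnitude module), runs seeded 30-second target-shooting
    rounds with a points/unlock reward economy and background-music
    pacing, and closes the loop with a configurable virtual-patient
    simulator for parameter-recovery testing. All session telemetry is
    tabular (tibbles, JSON-Lines logs) and fully reproducible from a
    seed.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
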