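Package: emogate
Title: Auditory Gating Analysis of Vocal Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for auditory gating experiments on vocal
    emotion recognition. Builds gated stimulus inventories and blocked
    presentation schedules from audio, scores five-alternative forced-choice
    responses with unbiased hit rates (Hu scores), extracts emotion
    identification points (EIPs) under a response-stability criterion,
    tabulates gate-frequency, cumulative-percent, error and latency summaries,
    and ships a psychometric synthetic-listener generator so every stage of
    the pipeline can be exercised and validated without access to raw
    behavioural data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
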