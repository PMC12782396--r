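# Independent oracles and small in-code fixtures shared across test files.

# Brute-force stabilization scan: tries every gate position as a candidate
# start and checks the whole suffix literally. Independent of identify_point.
bf_identify <- function(responses, target, full_duration_ms,
                        spec = gate_spec()) {
  n <- length(responses)
  for (g in seq_len(n)) {
    if (all(responses[g:n] == target)) {
      lab <- gate_labels(spec)[g]
      return(list(status = "identified", gate = lab,
                  eip_ms = gate_duration_ms(lab, spec, full_duration_ms)))
    }
  }
  list(status = "error", gate = NA_character_, eip_ms = NA_real_)
}

# Direct Hu evaluation from a raw count matrix (rows emotions, cols responses)
bf_hu <- function(counts, emotion) {
  tgt <- target_response(emotion)
  A <- counts[emotion, tgt]
  B <- sum(counts[emotion, ])
  C <- sum(counts[, tgt])
  if (A == 0) 0 else A^2 / (B * C)
}

# A tiny handmade dataset: 2 participants, 2 items, full gate coverage.
tiny_dataset <- function() {
  participants <- tibble::tibble(
    participant_id = c("arab_p01", "chinese_p01"),
    group = c("arab", "chinese")
  )
  items <- tibble::tibble(
    item_id = c("pro1", "voc1"),
    event_type = c("prosody", "vocalization"),
    language = c("english", "none"),
    emotion = c("sadness", "anger"),
    speaker_id = NA_character_,
    full_duration_ms = c(2000, 1448)
  )
  gates <- gate_labels(gate_spec())
  records <- tidyr::crossing(
    participant_id = participants$participant_id,
    item_id = items$item_id, gate = gates
  ) |>
    dplyr::mutate(
      response = ifelse(.data$item_id == "voc1", "anger", "sadness"),
      confidence = 5L
    )
  response_dataset(participants, items, records)
}

# A small random-but-valid dataset via a scaled-down generator config.
small_config <- function(seed, n_participants = 3, n_items = 4) {
  conditions <- tibble::tibble(
    event_type = c("vocalization", "prosody", "prosody"),
    language = c("none", "english", "mandarin"),
    emotion = c("anger", "sadness", "happiness"),
    n_items = n_items, dur_min_ms = 715, dur_max_ms = 2376,
    t50_ms = c(300, 700, 900), slope = 2.5, lapse = 0.05,
    neutral_bias = 0.5, stickiness = 0.9
  )
  generator_config(
    groups = tibble::tibble(group = c("chinese", "arab"),
                            n_participants = n_participants),
    conditions = conditions, seed = seed
  )
}

expect_dataset_equal <- function(a, b) {
  expect_identical(a$records, b$records)
  expect_identical(
    a$participants[c("participant_id", "group")],
    b$participants[c("participant_id", "group")]
  )
  keep <- setdiff(names(a$items), "speaker_id")
  expect_identical(as.data.frame(a$items[keep]), as.data.frame(b$items[keep]))
  expect_identical(gate_labels(a$gate_spec), gate_labels(b$gate_spec))
}
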