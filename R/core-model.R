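#' Trial-response dataset container
#'
#' Bundles the three long-format tables of a gating experiment — participants,
#' stimulus items, and per-trial responses — with the gate specification they
#' were collected under. Construction performs only structural coercion;
#' referential and label invariants are checked by [validate_dataset()], so
#' deliberately faulty datasets can be built for testing.
#'
#' @param participants Tibble with columns `participant_id`, `group`, and
#'   optionally `native_language`, `l2_proficiency`.
#' @param items Tibble with columns `item_id`, `event_type`, `language`,
#'   `emotion`, `speaker_id`, `full_duration_ms`.
#' @param records Tibble with columns `participant_id`, `item_id`, `gate`,
#'   `response`, `confidence`.
#' @param gate_spec A [gate_spec()].
#' @return An object of class `response_dataset`.
#' @export
response_dataset <- function(participants, items, records,
                             gate_spec = emogate::gate_spec()) {
  stopifnot(inherits(gate_spec, "gate_spec"))
  participants <- tibble::as_tibble(participants)
  items <- tibble::as_tibble(items)
  records <- tibble::as_tibble(records)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      abort_emogate(
        paste0("missing ", what, " column(s): ", paste(miss, collapse = ", ")),
        class = "emogate_schema_error"
      )
    }
  }
  need(participants, c("participant_id", "group"), "participant")
  need(items, c("item_id", "event_type", "language", "emotion",
                "speaker_id", "full_duration_ms"), "item")
  need(records, c("participant_id", "item_id", "gate", "response",
                  "confidence"), "record")
  structure(
    list(participants = participants, items = items,
         records = records, gate_spec = gate_spec),
    class = "response_dataset"
  )
}

#' @export
print.response_dataset <- function(x, ...) {
  cat("<response_dataset> ",
      nrow(x$participants), " participants, ",
      nrow(x$items), " items, ",
      nrow(x$records), " records; gates ",
      format(x$gate_spec), "\n", sep = "")
  invisible(x)
}

#' Validate a response dataset
#'
#' Checks every structural invariant of the data model and reports all
#' violations found, without raising errors: violations are data. An empty
#' report means the dataset is valid.
#'
#' Checked invariants: unique participant ids; legal event-type, language and
#' emotion labels; prosody items carry a real language and vocalizations carry
#' `none`; the happiness subtypes occur only as vocalizations; full durations
#' exceed the largest finite gate; records reference known participants,
#' items, and gate labels; responses come from the closed five-label set;
#' confidence, when present, lies in 1..7; at most one record per
#' participant x item x gate.
#'
#' @param dataset A [response_dataset()].
#' @return A tibble with columns `rule`, `id`, `message`; zero rows if valid.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "response_dataset"))
  p <- dataset$participants
  it <- dataset$items
  r <- dataset$records
  labs <- gate_labels(dataset$gate_spec)
  v <- list()
  add <- function(rule, id, message) {
    if (length(id) > 0) {
      v[[length(v) + 1]] <<- tibble::tibble(
        rule = rule, id = as.character(id), message = message
      )
    }
  }

  dup_p <- unique(p$participant_id[duplicated(p$participant_id)])
  add("duplicate_participant", dup_p, "participant_id not unique")

  bad <- it$item_id[!it$event_type %in% event_type_labels()]
  add("bad_event_type", bad, "event_type not in {vocalization, prosody}")
  bad <- it$item_id[!it$language %in% language_labels()]
  add("bad_language", bad, "unknown language label")
  bad <- it$item_id[!it$emotion %in% emotion_labels()]
  add("bad_emotion", bad, "unknown emotion category")
  bad <- it$item_id[it$event_type == "prosody" & it$language == "none"]
  add("prosody_needs_language", bad, "prosody item with language 'none'")
  bad <- it$item_id[it$event_type == "vocalization" & it$language != "none"]
  add("vocalization_language", bad, "vocalization item with a spoken language")
  bad <- it$item_id[it$event_type == "prosody" &
                      it$emotion %in% c("happiness_amusement", "happiness_pleasure")]
  add("happiness_subtype_event", bad,
      "happiness subtypes occur only as vocalizations")
  max_gate <- if (length(dataset$gate_spec$finite_gates_ms) > 0) {
    max(dataset$gate_spec$finite_gates_ms)
  } else {
    0
  }
  bad <- it$item_id[!is.na(it$full_duration_ms) & it$full_duration_ms <= max_gate]
  add("item_too_short", bad,
      paste0("full_duration_ms must exceed the largest finite gate (",
             max_gate, " ms)"))

  bad <- which(!r$participant_id %in% p$participant_id)
  add("unknown_participant", bad, "record references unknown participant")
  bad <- which(!r$item_id %in% it$item_id)
  add("unknown_item", bad, "record references unknown item")
  bad <- which(!r$gate %in% labs)
  add("unknown_gate", bad, "record uses a gate label outside the spec")
  bad <- which(!r$response %in% response_labels())
  add("bad_response", bad, "response outside the closed five-label set")
  bad <- which(!is.na(r$confidence) &
                 (r$confidence < 1 | r$confidence > 7 |
                    r$confidence != floor(r$confidence)))
  add("bad_confidence", bad, "confidence must be an integer in 1..7")
  key <- paste(r$participant_id, r$item_id, r$gate, sep = "\r")
  bad <- which(duplicated(key))
  add("duplicate_record", bad,
      "more than one record for a participant x item x gate")

  if (length(v) == 0) {
    tibble::tibble(rule = character(), id = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

canonical_columns <- function() {
  c("participant", "group", "event_type", "language", "emotion",
    "item", "gate", "response", "confidence", "full_duration_ms")
}

#' Read a long-format trial-response table
#'
#' Reads delimited text (comma by default, tab accepted) with one row per
#' judgment and reconstructs a validated [response_dataset()]. External
#' deposits with other column names are bridged through `dialect$col_map`, a
#' named character vector mapping canonical names to the file's names — the
#' import mapping is configured explicitly, never guessed.
#'
#' @param path File to read.
#' @param dialect Optional list: `delim` (default `","`), `col_map` (named
#'   character vector, canonical -> file column name).
#' @param gate_spec Gate specification the data were collected under.
#' @return A validated [response_dataset()].
#' @export
read_response_table <- function(path, dialect = NULL,
                                gate_spec = emogate::gate_spec()) {
  delim <- dialect$delim %||% ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  if (!is.null(dialect$col_map)) {
    cm <- dialect$col_map
    hit <- cm[cm %in% names(raw)]
    names(raw)[match(hit, names(raw))] <- names(hit)
  }
  miss <- setdiff(canonical_columns(), names(raw))
  if (length(miss) > 0) {
    abort_emogate(
      paste0("missing required column(s): ", paste(miss, collapse = ", ")),
      class = "emogate_schema_error"
    )
  }
  raw <- raw[canonical_columns()]
  raw$confidence <- suppressWarnings(as.integer(raw$confidence))
  raw$full_duration_ms <- suppressWarnings(as.numeric(raw$full_duration_ms))

  check_labels <- function(col, allowed, what) {
    bad <- which(!raw[[col]] %in% allowed)
    if (length(bad) > 0) {
      abort_emogate(
        paste0("unknown ", what, " '", raw[[col]][bad[1]], "' at row ", bad[1]),
        class = "emogate_validation_error"
      )
    }
  }
  check_labels("gate", gate_labels(gate_spec), "gate label")
  check_labels("response", response_labels(), "response label")
  check_labels("emotion", emotion_labels(), "emotion category")
  check_labels("event_type", event_type_labels(), "event type")
  check_labels("language", language_labels(), "language label")

  key <- paste(raw$participant, raw$item, raw$gate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort_emogate(
      paste0("duplicate participant x item x gate at row ", dup[1]),
      class = "emogate_duplication_error"
    )
  }

  items <- dplyr::distinct(
    raw, item_id = .data$item, event_type = .data$event_type,
    language = .data$language, emotion = .data$emotion,
    full_duration_ms = .data$full_duration_ms
  )
  clash <- items$item_id[duplicated(items$item_id)]
  if (length(clash) > 0) {
    abort_emogate(
      paste0("item '", clash[1], "' has conflicting metadata across rows"),
      class = "emogate_validation_error"
    )
  }
  items$speaker_id <- NA_character_
  items <- items[c("item_id", "event_type", "language", "emotion",
                   "speaker_id", "full_duration_ms")]
  items <- dplyr::arrange(items, .data$item_id)

  participants <- dplyr::distinct(
    raw, participant_id = .data$participant, group = .data$group
  )
  clash <- participants$participant_id[duplicated(participants$participant_id)]
  if (length(clash) > 0) {
    abort_emogate(
      paste0("participant '", clash[1], "' listed under more than one group"),
      class = "emogate_validation_error"
    )
  }
  participants <- dplyr::arrange(participants, .data$participant_id)

  records <- tibble::tibble(
    participant_id = raw$participant, item_id = raw$item, gate = raw$gate,
    response = raw$response, confidence = raw$confidence
  )
  records <- dplyr::arrange(records, .data$participant_id, .data$item_id,
                            gate_index(.data$gate, gate_spec))

  ds <- response_dataset(participants, items, records, gate_spec)
  rep <- validate_dataset(ds)
  if (nrow(rep) > 0) {
    abort_emogate(
      paste0("dataset fails validation: ", rep$rule[1], " (", rep$message[1], ")"),
      class = "emogate_validation_error"
    )
  }
  ds
}

#' Write a dataset as a long-format trial-response table
#'
#' Emits the canonical delimited layout (one row per judgment, header
#' required, UTF-8) with stable row ordering by participant, item, gate, so
#' that `write` then `read` is the identity on validated datasets.
#'
#' @param dataset A validated [response_dataset()].
#' @param path Output file.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(dataset, path, delim = ",") {
  stopifnot(inherits(dataset, "response_dataset"))
  rep <- validate_dataset(dataset)
  if (nrow(rep) > 0) {
    abort_emogate(paste0("refusing to write an invalid dataset: ", rep$rule[1]),
                  class = "emogate_validation_error")
  }
  flat <- dataset$records |>
    dplyr::left_join(dataset$items, by = "item_id") |>
    dplyr::left_join(dataset$participants[c("participant_id", "group")],
                     by = "participant_id") |>
    dplyr::transmute(
      participant = .data$participant_id, group = .data$group,
      event_type = .data$event_type, language = .data$language,
      emotion = .data$emotion, item = .data$item_id, gate = .data$gate,
      response = .data$response, confidence = .data$confidence,
      full_duration_ms = .data$full_duration_ms
    ) |>
    dplyr::arrange(.data$participant, .data$item,
                   gate_index(.data$gate, dataset$gate_spec))
  readr::write_delim(flat, path, delim = delim, na = "")
  invisible(path)
}
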