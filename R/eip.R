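# Emotion Identification Points: the earliest gate at which a listener gives
# the target label and never deviates from it at any longer exposure of the
# same item, expressed in milliseconds (finite gate duration, or the item's
# full duration when recognition first stabilizes at the full expression).

#' Identify the stabilization point of one participant x item
#'
#' Scans the per-gate responses in ascending duration order for the earliest
#' gate `g` such that the response at `g` and at every later gate equals the
#' target. Items whose target is never stably identified by the full-duration
#' gate are scored as errors (and excluded from latency summaries
#' downstream); sequences missing any gate's response are `incomplete`. Any
#' non-target response — another emotion or "neutral" — breaks stability.
#'
#' @param responses Named character vector: names are gate labels, values the
#'   response at each gate, supplied in ascending duration order.
#' @param target Target response label of the item.
#' @param full_duration_ms The item's full duration, used as the latency of a
#'   GFULL identification.
#' @param spec A [gate_spec()].
#' @return One-row tibble: `status` (`identified`/`error`/`incomplete`),
#'   `identification_gate`, `eip_ms`.
#' @export
#' @examples
#' identify_point(
#'   c(G200 = "anger", G400 = "anger", G500 = "fear",
#'     G600 = "anger", GFULL = "anger"),
#'   target = "anger", full_duration_ms = 1448
#' ) # stabilizes only at G600 -> 600 ms
identify_point <- function(responses, target, full_duration_ms,
                           spec = gate_spec()) {
  gates <- names(responses)
  if (is.null(gates) || any(!nzchar(gates))) {
    abort_emogate("responses must be named by gate label")
  }
  idx <- gate_index(gates, spec)
  if (anyNA(idx)) {
    abort_emogate(paste0("unknown gate label(s): ",
                         paste(gates[is.na(idx)], collapse = ", ")))
  }
  if (anyDuplicated(gates)) abort_emogate("duplicate gate labels in responses")
  if (is.unsorted(idx, strictly = TRUE)) {
    abort_emogate("responses must be ordered by ascending gate duration")
  }
  all_gates <- gate_labels(spec)
  if (length(gates) < length(all_gates) || anyNA(responses)) {
    return(tibble::tibble(status = "incomplete",
                          identification_gate = NA_character_,
                          eip_ms = NA_real_))
  }
  ok <- responses == target
  stable <- rev(cumprod(rev(ok))) == 1  # TRUE where every later gate is target too
  if (!any(stable)) {
    return(tibble::tibble(status = "error",
                          identification_gate = NA_character_,
                          eip_ms = NA_real_))
  }
  g <- gates[which(stable)[1]]
  tibble::tibble(
    status = "identified",
    identification_gate = g,
    eip_ms = gate_duration_ms(g, spec, full_duration_ms)
  )
}

#' EIP records for every participant x item of a dataset
#'
#' Applies the stability rule to each participant x item response sequence.
#' Pairs missing any gate's response are reported with status `incomplete`
#' and excluded from both frequencies and error counts downstream. All
#' stimulus categories are tabulated here — including happiness-pleasure,
#' which latency summaries drop by default (see [eip_summary()]).
#'
#' @param dataset A validated [response_dataset()].
#' @param include_categories Optional character vector restricting the
#'   stimulus emotion categories scored.
#' @return Tibble: `participant_id`, `item_id`, `group`, `event_type`,
#'   `language`, `emotion`, `status`, `identification_gate`, `eip_ms`,
#'   `full_duration_ms`.
#' @export
eip_table <- function(dataset, include_categories = NULL) {
  spec <- dataset$gate_spec
  all_gates <- gate_labels(spec)
  n_g <- length(all_gates)
  flat <- flatten_dataset(dataset)
  if (!is.null(include_categories)) {
    flat <- flat[flat$emotion %in% include_categories, ]
  }
  if (nrow(flat) == 0) {
    return(tibble::tibble(
      participant_id = character(), item_id = character(), group = character(),
      event_type = character(), language = character(), emotion = character(),
      status = character(), identification_gate = character(),
      eip_ms = numeric(), full_duration_ms = numeric()
    ))
  }
  flat$ok <- flat$response == target_response(flat$emotion)
  wide <- flat |>
    dplyr::select("participant_id", "item_id", "group", "event_type",
                  "language", "emotion", "full_duration_ms", "gate", "ok") |>
    tidyr::pivot_wider(names_from = "gate", values_from = "ok")
  present <- intersect(all_gates, names(wide))
  for (g in setdiff(all_gates, present)) wide[[g]] <- NA
  okm <- as.matrix(wide[all_gates])          # logical, NA where trial absent
  incomplete <- rowSums(is.na(okm)) > 0
  # suffix-stability: stable[, j] <=> target at every gate >= j
  stable <- okm
  if (n_g > 1) {
    for (j in (n_g - 1):1) stable[, j] <- okm[, j] & stable[, j + 1]
  }
  first_stable <- apply(stable, 1, function(z) {
    w <- which(z)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  status <- dplyr::case_when(
    incomplete ~ "incomplete",
    is.na(first_stable) ~ "error",
    TRUE ~ "identified"
  )
  gate_id <- ifelse(status == "identified", all_gates[first_stable],
                    NA_character_)
  out <- wide |>
    dplyr::select("participant_id", "item_id", "group", "event_type",
                  "language", "emotion", "full_duration_ms") |>
    dplyr::mutate(
      status = status,
      identification_gate = gate_id,
      eip_ms = ifelse(
        status == "identified",
        gate_duration_ms(dplyr::coalesce(gate_id, all_gates[1]), spec,
                         .data$full_duration_ms),
        NA_real_
      )
    ) |>
    dplyr::relocate("full_duration_ms", .after = "eip_ms") |>
    dplyr::arrange(.data$participant_id, .data$item_id)
  out
}

#' Gate-frequency / cumulative-percent / error / latency table
#'
#' For each cell (default: group x event type x language x emotion) counts
#' identifications at each gate, the cumulative percent identified by that
#' gate, the error fraction (target never stably identified by the
#' full-duration gate), and the mean and SD of the identification latency in
#' ms over identified items only. Percents are integer-rounded half-up.
#' Incomplete records are excluded from both totals and errors.
#'
#' @param records EIP records from [eip_table()].
#' @param by Cell-defining fields.
#' @param spec A [gate_spec()].
#' @return Tibble, one row per cell x gate, with per-cell columns
#'   `n_total`, `n_errors`, `error_pct`, `eip_mean_ms`, `eip_sd_ms` and
#'   per-gate columns `n_identified`, `cum_identified`, `cum_pct`.
#' @export
gate_frequency_table <- function(records,
                                 by = c("group", "event_type", "language",
                                        "emotion"),
                                 spec = gate_spec()) {
  labs <- gate_labels(spec)
  rec <- records[records$status != "incomplete", ]
  if (nrow(rec) == 0) abort_emogate("no complete EIP records to tabulate")
  cells <- rec |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_errors = sum(.data$status == "error"),
      error_pct = round_half_up(100 * .data$n_errors / .data$n_total),
      eip_mean_ms = mean(.data$eip_ms[.data$status == "identified"]),
      eip_sd_ms = stats::sd(.data$eip_ms[.data$status == "identified"]),
      .groups = "drop"
    )
  per_gate <- rec |>
    dplyr::filter(.data$status == "identified") |>
    dplyr::count(dplyr::across(dplyr::all_of(by)),
                 gate = factor(.data$identification_gate, levels = labs),
                 name = "n_identified", .drop = FALSE) |>
    dplyr::filter(!is.na(.data$gate)) |>
    dplyr::mutate(gate = as.character(.data$gate))
  out <- dplyr::inner_join(cells, per_gate, by = by) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::arrange(match(.data$gate, labs), .by_group = TRUE) |>
    dplyr::mutate(
      cum_identified = cumsum(.data$n_identified),
      cum_pct = round_half_up(100 * .data$cum_identified / .data$n_total)
    ) |>
    dplyr::ungroup()
  out
}

#' Mean and SD of identification latency per group of records
#'
#' Summarizes `eip_ms` over identified records only. Happiness-pleasure is
#' excluded by default, mirroring its exclusion from latency models (its
#' stimuli were overwhelmingly labelled neutral); pass
#' `exclude_categories = NULL` to keep it. Per-record full durations remain
#' available in [eip_table()] output so downstream models can covary
#' stimulus length.
#'
#' @param records EIP records from [eip_table()].
#' @param grouping Fields to summarize within.
#' @param exclude_categories Stimulus categories dropped before summarizing.
#' @return Tibble with `n_identified`, `eip_mean_ms`, `eip_sd_ms`; groups
#'   with no identified records are reported with `NA` latency.
#' @export
eip_summary <- function(records,
                        grouping = c("group", "event_type", "language",
                                     "emotion"),
                        exclude_categories = "happiness_pleasure") {
  rec <- records
  if (!is.null(exclude_categories)) {
    rec <- rec[!rec$emotion %in% exclude_categories, ]
  }
  rec |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n_identified = sum(.data$status == "identified"),
      eip_mean_ms = ifelse(.data$n_identified == 0, NA_real_,
                           mean(.data$eip_ms[.data$status == "identified"])),
      eip_sd_ms = ifelse(.data$n_identified < 2, NA_real_,
                         stats::sd(.data$eip_ms[.data$status == "identified"])),
      .groups = "drop"
    )
}
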