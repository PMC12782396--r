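# Forced-choice scoring: confusion matrices, unbiased hit rates (Hu),
# neutral-response proportions, confidence summaries.

flatten_dataset <- function(dataset) {
  dataset$records |>
    dplyr::left_join(dataset$items, by = "item_id") |>
    dplyr::left_join(dataset$participants[c("participant_id", "group")],
                     by = "participant_id")
}

#' Stratified stimulus-by-response confusion matrices
#'
#' Cross-tabulates stimulus emotion category against the five response labels
#' within each stratum defined by `stratifiers`. Rows are the emotion
#' categories presented in the stratum (there is no neutral stimulus row:
#' neutral is a response option only); columns are always the five response
#' labels. The sum of all cells equals the number of records in the stratum.
#'
#' @param dataset A validated [response_dataset()].
#' @param stratifiers Field names from the flattened record table (e.g.
#'   `group`, `event_type`, `language`, `gate`, `participant_id`).
#' @return A list of `confusion_matrix` objects, each with `$stratum`
#'   (one-row tibble) and `$counts` (emotion x response integer matrix).
#' @export
confusion_matrix <- function(dataset,
                             stratifiers = c("group", "event_type",
                                             "language", "gate")) {
  flat <- flatten_dataset(dataset)
  miss <- setdiff(stratifiers, names(flat))
  if (length(miss) > 0) {
    abort_emogate(paste0("unknown stratifier(s): ", paste(miss, collapse = ", ")))
  }
  keys <- dplyr::distinct(flat[stratifiers]) |>
    dplyr::arrange(dplyr::across(dplyr::everything()))
  purrr::map(seq_len(nrow(keys)), function(i) {
    key <- keys[i, , drop = FALSE]
    sub <- dplyr::inner_join(flat, key, by = stratifiers)
    emos <- sort(unique(sub$emotion))
    counts <- table(
      factor(sub$emotion, levels = emos),
      factor(sub$response, levels = response_labels())
    )
    m <- matrix(as.integer(counts), nrow = length(emos),
                dimnames = list(emotion = emos, response = response_labels()))
    structure(list(stratum = key, counts = m), class = "confusion_matrix")
  })
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> ",
      paste(names(x$stratum), unlist(x$stratum), sep = "=", collapse = ", "),
      "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Unbiased hit rate (Hu score) for one emotion in one stratum
#'
#' Wagner's unbiased hit rate `Hu = A^2 / (B * C)`, where `A` is the number
#' of target responses given to the emotion's stimuli, `B` the number of
#' presentations of that emotion, and `C` the total number of uses of the
#' emotion's target response label anywhere in the stratum. Equivalently
#' `Hu = (A/B) * (A/C)`: raw hit rate times precision, which corrects raw
#' accuracy for both category frequency and the responder's label-usage bias.
#' When the target label is never used (`A = C = 0`), Hu is 0 by convention.
#'
#' @param matrix A `confusion_matrix` from [confusion_matrix()].
#' @param emotion A stimulus emotion category present in the matrix rows.
#' @return A proportion in \[0, 1\].
#' @export
#' @examples
#' # A = 6 of B = 10 presentations correct, target label used C = 12 times
#' # => Hu = 36 / 120 = 0.30
hu_score <- function(matrix, emotion) {
  stopifnot(inherits(matrix, "confusion_matrix"))
  if (!emotion %in% rownames(matrix$counts)) {
    abort_emogate(paste0("emotion '", emotion, "' is not a row of this matrix"))
  }
  tgt <- target_response(emotion)
  A <- matrix$counts[emotion, tgt]
  B <- sum(matrix$counts[emotion, ])
  C <- sum(matrix$counts[, tgt])
  if (B == 0) abort_emogate(paste0("no presentations of '", emotion,
                                   "' in this stratum (B = 0)"))
  if (A == 0) return(0)
  as.numeric(A^2 / (B * C))
}

#' Per-participant Hu scores across the whole design
#'
#' Computes the unbiased hit rate for every participant x emotion x gate
#' within each event condition (event type x language): `A`, `B` and the
#' bias term `C` are counted over that participant's responses in the
#' stratum, so `C` reflects the participant's own usage of the target label
#' at that gate and condition. Averaging entries over participants
#' reproduces the accuracy-trajectory layout of the published tables.
#'
#' @param dataset A validated [response_dataset()].
#' @return A tibble (`hu_table`): `participant_id`, `group`, `event_type`,
#'   `language`, `gate`, `emotion`, `A`, `B`, `C`, `hu`.
#' @export
hu_table <- function(dataset) {
  flat <- flatten_dataset(dataset)
  strat <- c("participant_id", "group", "event_type", "language", "gate")
  # label usage per stratum: C for each response label
  usage <- flat |>
    dplyr::count(dplyr::across(dplyr::all_of(strat)), .data$response,
                 name = "C")
  out <- flat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(strat, "emotion")))) |>
    dplyr::summarise(
      A = sum(.data$response == target_response(.data$emotion[1])),
      B = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(target = target_response(.data$emotion)) |>
    dplyr::left_join(usage, by = c(strat, target = "response")) |>
    dplyr::mutate(
      C = dplyr::coalesce(.data$C, 0L),
      hu = dplyr::if_else(.data$A == 0, 0, .data$A^2 / (.data$B * .data$C))
    ) |>
    dplyr::select(-"target") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(strat, "emotion"))))
  class(out) <- c("hu_table", class(out))
  out
}

#' Proportion of neutral responses per stratum
#'
#' Emotional voices tend to be labelled "neutral" at brief exposures; this
#' summary tracks that pattern by emotion, gate, and condition.
#'
#' @param dataset A validated [response_dataset()].
#' @param stratifiers Grouping fields (flattened record table).
#' @return Tibble with `n`, `n_neutral`, `prop_neutral` per stratum.
#' @export
neutral_proportion <- function(dataset,
                               stratifiers = c("group", "event_type",
                                               "language", "emotion", "gate")) {
  flat <- flatten_dataset(dataset)
  flat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(stratifiers))) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_neutral = sum(.data$response == "neutral"),
      prop_neutral = .data$n_neutral / .data$n,
      .groups = "drop"
    )
}

#' Mean confidence ratings per stratum
#'
#' Arithmetic mean of the 1-7 confidence ratings; missing ratings are
#' excluded, and a stratum with no ratings at all is reported as `NA`, not
#' zero.
#'
#' @param dataset A validated [response_dataset()].
#' @param stratifiers Grouping fields (flattened record table).
#' @return Tibble with `n_rated` and `mean_confidence` per stratum.
#' @export
confidence_summary <- function(dataset,
                               stratifiers = c("group", "event_type",
                                               "language", "emotion", "gate")) {
  flat <- flatten_dataset(dataset)
  flat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(stratifiers))) |>
    dplyr::summarise(
      n_rated = sum(!is.na(.data$confidence)),
      mean_confidence = ifelse(.data$n_rated == 0, NA_real_,
                               mean(.data$confidence, na.rm = TRUE)),
      .groups = "drop"
    )
}
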