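# Publication-style tables, language-familiarity recoding, descriptive
# bootstrap contrasts, and the model-ready export for external mixed-model
# fitting (the models themselves are delegated to standard tooling such as
# lme4/lmerTest/emmeans).

familiarity_map <- function() {
  tibble::tibble(
    group = rep(c("chinese", "arab"), each = 3),
    language = c("mandarin", "english", "arabic",
                 "arabic", "english", "mandarin"),
    familiarity = rep(c("native", "L2", "foreign"), 2)
  )
}

#' Accuracy-trajectory table (participant-mean Hu, gates as columns)
#'
#' Averages Hu scores over participants within group x event type x language
#' x emotion and lays gates out as columns, the layout used to report
#' recognition-accuracy trajectories.
#'
#' @param hu A [hu_table()].
#' @param spec A [gate_spec()] (controls gate column order).
#' @return A wide tibble, one row per group x condition x emotion.
#' @export
accuracy_trajectory_table <- function(hu, spec = gate_spec()) {
  hu |>
    dplyr::group_by(.data$group, .data$event_type, .data$language,
                    .data$emotion, .data$gate) |>
    dplyr::summarise(mean_hu = mean(.data$hu), .groups = "drop") |>
    dplyr::mutate(gate = factor(.data$gate, levels = gate_labels(spec))) |>
    dplyr::arrange(.data$group, .data$event_type, .data$language,
                   .data$emotion, .data$gate) |>
    tidyr::pivot_wider(names_from = "gate", values_from = "mean_hu")
}

#' Derive language familiarity from perceiver group and stimulus language
#'
#' Chinese listeners: mandarin is native, english L2, arabic foreign; Arab
#' listeners: arabic native, english L2, mandarin foreign. Vocalizations
#' (language `none`) have no familiarity level — the factor is left `NA`,
#' since nonverbal events are their own condition. The mapping is a bijection
#' per group between the three spoken languages and
#' \{native, L2, foreign\}; [relabel_language()] is its inverse.
#'
#' @param x A data frame with the group and language columns.
#' @param group_col,language_col Column names.
#' @return `x` with a `familiarity` column added.
#' @export
relabel_familiarity <- function(x, group_col = "group",
                                language_col = "language") {
  fm <- familiarity_map()
  langs <- x[[language_col]]
  groups <- x[[group_col]]
  spoken <- langs != "none"
  known <- paste(fm$group, fm$language)
  bad <- unique(paste(groups, langs)[spoken &
                                       !paste(groups, langs) %in% known])
  if (length(bad) > 0) {
    abort_emogate(paste0("no familiarity mapping for group x language: ",
                         paste(bad, collapse = "; ")))
  }
  idx <- match(paste(groups, langs), known)
  x$familiarity <- fm$familiarity[idx]
  x
}

#' @rdname relabel_familiarity
#' @param familiarity_col Column holding familiarity levels.
#' @return `relabel_language()`: `x` with a `language` column recovered from
#'   group and familiarity.
#' @export
relabel_language <- function(x, group_col = "group",
                             familiarity_col = "familiarity") {
  fm <- familiarity_map()
  key <- paste(x[[group_col]], x[[familiarity_col]])
  known <- paste(fm$group, fm$familiarity)
  fam <- x[[familiarity_col]]
  bad <- unique(key[!is.na(fam) & !key %in% known])
  if (length(bad) > 0) {
    abort_emogate(paste0("no language mapping for group x familiarity: ",
                         paste(bad, collapse = "; ")))
  }
  idx <- match(key, known)
  x$language <- ifelse(is.na(fam), "none", fm$language[idx])
  x
}

#' Bootstrap contrast between two cells, resampling participants
#'
#' Difference of cell means with a seed-reproducible percentile confidence
#' interval. Participants — the exchangeable unit under a by-subject
#' random-effect structure — are resampled with replacement within each
#' cell; all rows of a drawn participant enter the resampled mean.
#'
#' @param values Data frame of model-ready rows.
#' @param cell_a,cell_b Named lists selecting rows, e.g.
#'   `list(event_type = "vocalization")`.
#' @param value_col,participant_col Column names of the measure and the
#'   participant identifier.
#' @param replicates Bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param conf Interval coverage (default 0.95, percentile method).
#' @return List: `estimate` (mean A - mean B), `lower`, `upper`,
#'   `replicates`, `n_a`, `n_b`.
#' @export
bootstrap_group_contrast <- function(values, cell_a, cell_b,
                                     value_col = "value",
                                     participant_col = "participant_id",
                                     replicates = 1000, seed = 1,
                                     conf = 0.95) {
  if (replicates < 100) abort_emogate("use at least 100 bootstrap replicates")
  pick <- function(sel) {
    keep <- rep(TRUE, nrow(values))
    for (nm in names(sel)) keep <- keep & values[[nm]] %in% sel[[nm]]
    df <- values[keep, c(participant_col, value_col)]
    names(df) <- c("pid", "y")
    df <- df[!is.na(df$y), ]
    if (nrow(df) == 0) abort_emogate("empty cell in bootstrap contrast")
    df
  }
  a <- pick(cell_a)
  b <- pick(cell_b)
  est <- mean(a$y) - mean(b$y)
  cell_mean <- function(df, pids) {
    # resample participants; each drawn participant contributes all rows
    mean(unlist(split(df$y, df$pid)[pids]))
  }
  withr::with_seed(seed, {
    pa <- unique(a$pid)
    pb <- unique(b$pid)
    diffs <- vapply(seq_len(replicates), function(i) {
      cell_mean(a, sample(pa, length(pa), replace = TRUE)) -
        cell_mean(b, sample(pb, length(pb), replace = TRUE))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(diffs, c(alpha, 1 - alpha), names = FALSE)
  list(estimate = est, lower = qs[1], upper = qs[2],
       replicates = replicates, n_a = nrow(a), n_b = nrow(b))
}

#' Export the model-ready long table
#'
#' Stacks Hu scores and EIP latencies into one long table with the column
#' names used by the mixed-model formulas (Group, EventType, Emotion, Gate,
#' Familiarity, GFullDuration): one row per Hu entry (Measure = "HuScore")
#' and one per identified EIP record (Measure = "EIPtime", carrying the
#' item's full duration so models can covary stimulus length). EventType
#' folds language familiarity into the four-level factor
#' vocalization/native/L2/foreign; Familiarity is blank for vocalizations.
#'
#' @param hu A [hu_table()].
#' @param eips EIP records from [eip_table()].
#' @param path Output file (CSV).
#' @return The table, invisibly (also written to `path`).
#' @export
export_model_table <- function(hu, eips, path) {
  hu_rows <- if (nrow(hu) > 0) {
    hu |>
      relabel_familiarity() |>
      dplyr::transmute(
        Measure = "HuScore", Participant = .data$participant_id,
        Group = .data$group,
        EventType = ifelse(.data$event_type == "vocalization",
                           "vocalization", .data$familiarity),
        Language = .data$language, Familiarity = .data$familiarity,
        Emotion = .data$emotion, Gate = .data$gate,
        Value = .data$hu, GFullDuration = NA_real_
      )
  } else {
    NULL
  }
  eip_rows <- if (nrow(eips) > 0) {
    eips |>
      dplyr::filter(.data$status == "identified") |>
      relabel_familiarity() |>
      dplyr::transmute(
        Measure = "EIPtime", Participant = .data$participant_id,
        Group = .data$group,
        EventType = ifelse(.data$event_type == "vocalization",
                           "vocalization", .data$familiarity),
        Language = .data$language, Familiarity = .data$familiarity,
        Emotion = .data$emotion, Gate = .data$identification_gate,
        Value = .data$eip_ms, GFullDuration = .data$full_duration_ms
      )
  } else {
    NULL
  }
  out <- dplyr::bind_rows(hu_rows, eip_rows)
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble::tibble(
      Measure = character(), Participant = character(), Group = character(),
      EventType = character(), Language = character(),
      Familiarity = character(), Emotion = character(), Gate = character(),
      Value = numeric(), GFullDuration = numeric()
    )
  }
  readr::write_csv(out, path, na = "")
  invisible(out)
}

#' Read back a model-ready table
#'
#' @param path CSV written by [export_model_table()].
#' @return A tibble with the exported columns and types.
#' @export
read_model_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    Measure = readr::col_character(), Participant = readr::col_character(),
    Group = readr::col_character(), EventType = readr::col_character(),
    Language = readr::col_character(), Familiarity = readr::col_character(),
    Emotion = readr::col_character(), Gate = readr::col_character(),
    Value = readr::col_double(), GFullDuration = readr::col_double()
  ), na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
}
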