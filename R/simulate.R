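# Synthetic listeners: a psychometric response generator with the same
# statistical structure the pipeline assumes, so every stage can be exercised
# and validated without access to raw behavioural data.

#' Condition-level response parameters
#'
#' @param t50_ms Latent identification threshold: stimulus duration at which
#'   target-recognition probability reaches 0.5 (ms, > 0).
#' @param slope Steepness of the psychometric curve on log-duration (> 0);
#'   `Inf` gives a step function (`p = 1` for durations >= `t50_ms`).
#' @param lapse Probability of a uniform random response over all 5 labels.
#' @param neutral_bias Weight of the "neutral" label at brief exposures,
#'   decaying exponentially with duration.
#' @param stickiness Probability of repeating the previous gate's response
#'   when that response was the target (models response stability; a
#'   modeling invention, not an empirically measured quantity).
#' @return A named list of class `condition_params`.
#' @export
condition_params <- function(t50_ms, slope = 2.5, lapse = 0.05,
                             neutral_bias = 0.5, stickiness = 0.9) {
  if (t50_ms <= 0) abort_emogate("t50_ms must be positive")
  if (slope <= 0) abort_emogate("slope must be positive")
  for (p in c(lapse = lapse, neutral_bias = neutral_bias,
              stickiness = stickiness)) {
    if (p < 0 || p > 1) {
      abort_emogate("lapse, neutral_bias and stickiness must lie in [0, 1]")
    }
  }
  structure(list(t50_ms = t50_ms, slope = slope, lapse = lapse,
                 neutral_bias = neutral_bias, stickiness = stickiness),
            class = "condition_params")
}

#' Generator configuration
#'
#' @param groups Tibble with columns `group`, `n_participants`.
#' @param conditions Tibble with one row per event type x language x emotion:
#'   `event_type`, `language`, `emotion`, `n_items`, `dur_min_ms`,
#'   `dur_max_ms`, `t50_ms`, `slope`, `lapse`, `neutral_bias`, `stickiness`.
#' @param gate_spec A [gate_spec()].
#' @param participant_sd,item_sd SD of normal random effects on `log(t50)`.
#' @param neutral_tau_ms e-folding duration of the neutral-bias decay.
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(groups, conditions, gate_spec = emogate::gate_spec(),
                             participant_sd = 0.15, item_sd = 0.2,
                             neutral_tau_ms = 600, seed) {
  if (missing(seed) || is.null(seed)) abort_emogate("seed is mandatory")
  groups <- tibble::as_tibble(groups)
  conditions <- tibble::as_tibble(conditions)
  stopifnot(all(c("group", "n_participants") %in% names(groups)))
  need <- c("event_type", "language", "emotion", "n_items", "dur_min_ms",
            "dur_max_ms", "t50_ms", "slope", "lapse", "neutral_bias",
            "stickiness")
  miss <- setdiff(need, names(conditions))
  if (length(miss) > 0) {
    abort_emogate(paste0("conditions missing column(s): ",
                         paste(miss, collapse = ", ")))
  }
  if (any(groups$n_participants < 1)) {
    abort_emogate("each group needs at least one participant")
  }
  if (any(conditions$t50_ms <= 0) || any(conditions$slope <= 0)) {
    abort_emogate("t50_ms and slope must be positive")
  }
  probs <- conditions[c("lapse", "neutral_bias", "stickiness")]
  if (any(unlist(probs) < 0) || any(unlist(probs) > 1)) {
    abort_emogate("lapse, neutral_bias and stickiness must lie in [0, 1]")
  }
  max_gate <- if (length(gate_spec$finite_gates_ms)) {
    max(gate_spec$finite_gates_ms)
  } else {
    0
  }
  if (any(conditions$dur_min_ms <= max_gate)) {
    abort_emogate("duration ranges must exceed the largest finite gate")
  }
  if (any(conditions$dur_max_ms < conditions$dur_min_ms)) {
    abort_emogate("dur_max_ms must be >= dur_min_ms")
  }
  structure(
    list(groups = groups, conditions = conditions, gate_spec = gate_spec,
         participant_sd = participant_sd, item_sd = item_sd,
         neutral_tau_ms = neutral_tau_ms, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Default configuration reproducing the study design counts
#'
#' Two listener groups (chinese, arab) x 25 participants; 50 vocalizations
#' (10 each of anger, fear, sadness, happiness-amusement,
#' happiness-pleasure) with full durations sampled uniformly in 715-2376 ms;
#' 144 pseudo-utterances (3 languages x 4 emotions x 12 items) in
#' 834-2900 ms; 5 gates (200/400/500/600/full). Psychometric thresholds are
#' chosen to emulate the qualitative pattern of the field — vocalizations
#' stabilizing within ~300-500 ms (anger earliest), prosody later and
#' happiness latest, happiness-pleasure rarely identified — but are not
#' fitted to any dataset.
#'
#' @param seed Integer seed.
#' @return A [generator_config()].
#' @export
default_config <- function(seed = 1L) {
  voc <- tibble::tibble(
    event_type = "vocalization", language = "none",
    emotion = c("anger", "fear", "sadness",
                "happiness_amusement", "happiness_pleasure"),
    n_items = 10L, dur_min_ms = 715, dur_max_ms = 2376,
    t50_ms = c(250, 450, 400, 350, 2200),
    slope = 2.5, lapse = 0.05,
    neutral_bias = c(0.5, 0.5, 0.5, 0.5, 0.9),
    stickiness = 0.9
  )
  pros <- tidyr::crossing(
    language = c("arabic", "mandarin", "english"),
    emotion = c("anger", "fear", "sadness", "happiness")
  ) |>
    dplyr::mutate(
      event_type = "prosody", n_items = 12L,
      dur_min_ms = 834, dur_max_ms = 2900,
      t50_ms = dplyr::case_when(
        emotion == "anger" ~ 650,
        emotion == "sadness" ~ 600,
        emotion == "fear" ~ 850,
        TRUE ~ 1100
      ),
      slope = 2.5, lapse = 0.05, neutral_bias = 0.5, stickiness = 0.9
    ) |>
    dplyr::select(dplyr::all_of(names(voc)))
  generator_config(
    groups = tibble::tibble(group = c("chinese", "arab"),
                            n_participants = 25L),
    conditions = dplyr::bind_rows(voc, pros),
    seed = seed
  )
}

# psychometric recognition probability on log-duration; Inf slope = step
p_target <- function(d_ms, t50_ms, slope) {
  step <- is.infinite(slope)
  p <- stats::plogis(slope * (log(d_ms) - log(t50_ms)))
  p[step] <- as.numeric(d_ms >= t50_ms)[step]
  p
}

#' Analytic response probabilities of the generator kernel
#'
#' The probability of each of the five response labels for a single draw,
#' given stimulus duration, condition parameters, and whether the previous
#' gate's response was the target. Used by [simulate_dataset()] (via its
#' inverse-CDF sampler) and directly testable: the five probabilities always
#' sum to 1.
#'
#' @param target Target response label of the item.
#' @param d_ms Playable duration of the trial (ms).
#' @param params A [condition_params()] (or compatible list).
#' @param prev_was_target Was the previous gate's response the target?
#' @param neutral_tau_ms Decay constant of the neutral bias (ms).
#' @return Named numeric vector over [response_labels()], summing to 1.
#' @export
response_probabilities <- function(target, d_ms, params,
                                   prev_was_target = FALSE,
                                   neutral_tau_ms = 600) {
  labs <- response_labels()
  p <- p_target(d_ms, params$t50_ms, params$slope)
  nf <- params$neutral_bias * exp(-d_ms / neutral_tau_ms)
  others <- setdiff(setdiff(labs, "neutral"), target)
  s <- if (prev_was_target) params$stickiness else 0
  # lapse is outermost: a lapsing listener guesses uniformly regardless of
  # stickiness, so lapse = 1 yields an exact 1/5 target rate at every gate
  k <- stats::setNames(rep(params$lapse / 5, 5), labs)
  k[target] <- k[target] + (1 - params$lapse) * (s + (1 - s) * p)
  k["neutral"] <- k["neutral"] + (1 - params$lapse) * (1 - s) * (1 - p) * nf
  k[others] <- k[others] + (1 - params$lapse) * (1 - s) * (1 - p) * (1 - nf) / 3
  k
}

#' Simulate a full response dataset
#'
#' For each participant x item x gate, in ascending gate order: with
#' probability `lapse` a uniform random label is given; otherwise, if the
#' previous gate's response was the target, it is repeated with probability
#' `stickiness`; otherwise the target is chosen with probability
#' `plogis(slope * (log d - log t50_eff))`, where `d` is the playable
#' duration and `t50_eff = t50 * exp(participant effect + item effect)`;
#' remaining mass goes to "neutral" (with weight `neutral_bias *
#' exp(-d / neutral_tau_ms)`, so neutral attraction fades with exposure) and
#' uniformly to the non-target emotion labels. Confidence ratings grow with
#' recognition probability. The same seed always yields the identical
#' dataset.
#'
#' @param config A [generator_config()].
#' @return A validated [response_dataset()].
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  spec <- config$gate_spec
  labs <- gate_labels(spec)
  withr::with_seed(config$seed, {
    participants <- purrr::map_dfr(seq_len(nrow(config$groups)), function(i) {
      g <- config$groups[i, ]
      tibble::tibble(
        participant_id = sprintf("%s_p%02d", g$group,
                                 seq_len(g$n_participants)),
        group = g$group
      )
    })
    items <- purrr::map_dfr(seq_len(nrow(config$conditions)), function(i) {
      cn <- config$conditions[i, ]
      tibble::tibble(
        item_id = sprintf("%s_%s_%s_i%02d", substr(cn$event_type, 1, 3),
                          cn$language, cn$emotion, seq_len(cn$n_items)),
        event_type = cn$event_type, language = cn$language,
        emotion = cn$emotion,
        speaker_id = sprintf("spk%02d", 1 + (seq_len(cn$n_items) %% 4)),
        full_duration_ms = round(stats::runif(cn$n_items, cn$dur_min_ms,
                                              cn$dur_max_ms)),
        t50_ms = cn$t50_ms, slope = cn$slope, lapse = cn$lapse,
        neutral_bias = cn$neutral_bias, stickiness = cn$stickiness
      )
    })
    p_eff <- stats::setNames(
      stats::rnorm(nrow(participants), 0, config$participant_sd),
      participants$participant_id
    )
    i_eff <- stats::setNames(
      stats::rnorm(nrow(items), 0, config$item_sd), items$item_id
    )
    grid <- tidyr::crossing(participant_id = participants$participant_id,
                            item_id = items$item_id) |>
      dplyr::left_join(items, by = "item_id") |>
      dplyr::arrange(.data$participant_id, .data$item_id)
    grid$t50_eff <- grid$t50_ms *
      exp(p_eff[grid$participant_id] + i_eff[grid$item_id])
    grid$target <- target_response(grid$emotion)
    n <- nrow(grid)
    emo4 <- setdiff(response_labels(), "neutral")
    # 3 non-target emotion labels per row, in sorted order
    other_mat <- t(vapply(grid$target,
                          function(tg) sort(setdiff(emo4, tg)),
                          character(3)))
    prev_resp <- rep(NA_character_, n)
    rec <- vector("list", length(labs))
    for (gi in seq_along(labs)) {
      g <- labs[gi]
      d <- gate_duration_ms(rep(g, n), spec, grid$full_duration_ms)
      p <- p_target(d, grid$t50_eff, grid$slope)
      nf <- grid$neutral_bias * exp(-d / config$neutral_tau_ms)
      s <- ifelse(!is.na(prev_resp) & prev_resp == grid$target,
                  grid$stickiness, 0)
      pt <- grid$lapse / 5 + (1 - grid$lapse) * (s + (1 - s) * p)
      pn <- grid$lapse / 5 + (1 - grid$lapse) * (1 - s) * (1 - p) * nf
      po <- grid$lapse / 5 + (1 - grid$lapse) * (1 - s) * (1 - p) * (1 - nf) / 3
      u <- stats::runif(n)
      resp <- character(n)
      hit <- u < pt
      resp[hit] <- grid$target[hit]
      rest <- !hit
      neu <- rest & u < pt + pn
      resp[neu] <- "neutral"
      oth <- rest & !neu
      oi <- pmin(3, 1 + floor((u[oth] - (pt + pn)[oth]) / po[oth]))
      oi[!is.finite(oi)] <- 1  # float edge when non-target mass ~ 0
      resp[oth] <- other_mat[cbind(which(oth), pmax(1, oi))]
      conf <- round(1 + 6 * p + stats::rnorm(n, 0, 0.8))
      conf <- pmin(7L, pmax(1L, as.integer(conf)))
      rec[[gi]] <- tibble::tibble(
        participant_id = grid$participant_id, item_id = grid$item_id,
        gate = g, response = resp, confidence = conf
      )
      prev_resp <- resp
    }
    records <- dplyr::bind_rows(rec) |>
      dplyr::arrange(.data$participant_id, .data$item_id,
                     gate_index(.data$gate, spec))
    response_dataset(
      dplyr::arrange(participants, .data$participant_id),
      dplyr::arrange(
        items[c("item_id", "event_type", "language", "emotion", "speaker_id",
                "full_duration_ms")],
        .data$item_id
      ),
      records, spec
    )
  })
}

#' Parameter-recovery study over a grid of configurations
#'
#' For each configuration and replicate, simulates a dataset, extracts EIPs
#' and Hu scores, and relates the estimated mean identification latency back
#' to the generating threshold `t50`. The Spearman rank correlation between
#' config-level mean `t50` and estimated mean EIP (per replicate, across
#' configs) summarizes recovery.
#'
#' @param config_grid List of [generator_config()]s.
#' @param replicates Number of simulation replicates per config (>= 1);
#'   replicate `r` of config `c` runs with seed `config$seed + 7919 * (r-1)`.
#' @return List of class `recovery_report`: `$runs` (per config x replicate
#'   mean EIP / mean Hu), `$by_condition` (per condition recovery pairs),
#'   `$spearman` (per replicate rank correlation).
#' @export
recovery_study <- function(config_grid, replicates = 1) {
  stopifnot(replicates >= 1, length(config_grid) >= 1)
  runs <- list()
  by_cond <- list()
  for (ci in seq_along(config_grid)) {
    base <- config_grid[[ci]]
    for (r in seq_len(replicates)) {
      cfg <- base
      cfg$seed <- as.integer(base$seed + 7919L * (r - 1L))
      ds <- simulate_dataset(cfg)
      eips <- eip_table(ds)
      hu <- hu_table(ds)
      idf <- eips[eips$status == "identified", ]
      runs[[length(runs) + 1]] <- tibble::tibble(
        config = ci, replicate = r,
        t50_mean = mean(cfg$conditions$t50_ms),
        mean_eip_ms = mean(idf$eip_ms),
        mean_hu = mean(hu$hu)
      )
      bc <- eip_summary(eips, grouping = c("event_type", "language", "emotion"),
                        exclude_categories = NULL) |>
        dplyr::left_join(
          cfg$conditions[c("event_type", "language", "emotion", "t50_ms")],
          by = c("event_type", "language", "emotion")
        ) |>
        dplyr::mutate(config = ci, replicate = r)
      by_cond[[length(by_cond) + 1]] <- bc
    }
  }
  runs <- dplyr::bind_rows(runs)
  spearman <- runs |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(
      rho = if (dplyr::n() < 2) NA_real_ else
        stats::cor(.data$t50_mean, .data$mean_eip_ms, method = "spearman"),
      .groups = "drop"
    )
  structure(list(runs = runs, by_condition = dplyr::bind_rows(by_cond),
                 spearman = spearman),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> ", nrow(x$runs), " runs; Spearman(t50, mean EIP): ",
      paste(format(x$spearman$rho, digits = 3), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Read / write generator configurations as YAML
#'
#' @param config A [generator_config()].
#' @param path File path.
#' @return `read_generator_config` returns a [generator_config()];
#'   `write_generator_config` returns `path` invisibly.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  obj <- list(
    groups = as.data.frame(config$groups),
    conditions = as.data.frame(config$conditions),
    gate_spec = list(finite_gates_ms = config$gate_spec$finite_gates_ms,
                     include_full = config$gate_spec$include_full),
    participant_sd = config$participant_sd, item_sd = config$item_sd,
    neutral_tau_ms = config$neutral_tau_ms, seed = config$seed
  )
  yaml::write_yaml(obj, path, column.major = FALSE)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  obj <- yaml::read_yaml(path)
  generator_config(
    groups = dplyr::bind_rows(obj$groups),
    conditions = dplyr::bind_rows(obj$conditions),
    gate_spec = gate_spec(obj$gate_spec$finite_gates_ms,
                          obj$gate_spec$include_full),
    participant_sd = obj$participant_sd, item_sd = obj$item_sd,
    neutral_tau_ms = obj$neutral_tau_ms, seed = obj$seed
  )
}
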