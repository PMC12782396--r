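#' In-memory mono waveform
#'
#' @param samples Numeric amplitudes in \[-1, 1\].
#' @param sample_rate_hz Positive integer sampling rate.
#' @return An object of class `waveform`.
#' @export
#' @examples
#' waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 16000)), 16000)
waveform <- function(samples, sample_rate_hz) {
  samples <- as.numeric(samples)
  if (length(samples) < 1) abort_emogate("waveform needs at least one sample")
  if (any(!is.finite(samples))) abort_emogate("waveform samples must be finite")
  if (max(abs(samples)) > 1 + 1e-9) {
    abort_emogate("waveform amplitudes must lie in [-1, 1]")
  }
  if (length(sample_rate_hz) != 1 || sample_rate_hz <= 0) {
    abort_emogate("sample_rate_hz must be a single positive number")
  }
  structure(list(samples = samples, sample_rate_hz = as.integer(sample_rate_hz)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat("<waveform> ", length(x$samples), " samples @ ", x$sample_rate_hz,
      " Hz (", round(1000 * length(x$samples) / x$sample_rate_hz, 1),
      " ms)\n", sep = "")
  invisible(x)
}

ms_to_samples <- function(ms, rate) {
  as.integer(round_half_up(ms * rate / 1000))
}

#' Cut a gated segment from acoustic onset
#'
#' Takes the initial `duration_ms` of the audio, measured from sample 0, with
#' a linear fade-out over the final `fade_ms` to suppress the click artefact a
#' hard cut would create. If the requested duration covers the whole
#' recording, the input is returned unchanged (no fade): the full-duration
#' gate is the unedited sound.
#'
#' @param audio A [waveform()].
#' @param duration_ms Gate duration in ms (> 0).
#' @param fade_ms Fade-out length in ms (>= 0, <= `duration_ms`); default 5.
#' @return A [waveform()].
#' @export
cut_segment <- function(audio, duration_ms, fade_ms = 5) {
  stopifnot(inherits(audio, "waveform"))
  if (duration_ms <= 0) abort_emogate("duration_ms must be positive")
  if (fade_ms < 0) abort_emogate("fade_ms must be nonnegative")
  if (fade_ms > duration_ms) abort_emogate("fade_ms cannot exceed duration_ms")
  n <- ms_to_samples(duration_ms, audio$sample_rate_hz)
  if (n >= length(audio$samples)) {
    return(audio)
  }
  s <- audio$samples[seq_len(n)]
  m <- ms_to_samples(fade_ms, audio$sample_rate_hz)
  if (m > 0) {
    m <- min(m, n)
    # ramp (m-1)/m, ..., 1/m, 0: last sample reaches exactly zero
    ramp <- (m - seq_len(m)) / m
    s[(n - m + 1):n] <- s[(n - m + 1):n] * ramp
  }
  waveform(s, audio$sample_rate_hz)
}

#' Normalize peak amplitude
#'
#' Rescales the waveform by a single positive factor so its peak magnitude
#' equals the target level. The target is interpreted as a linear amplitude
#' ratio when given in (0, 1\], or as dBFS when <= 0 (e.g. `-3` means
#' `10^(-3/20)`). Peak standardization of a digital file is the reproducible
#' counterpart of equating playback sound-pressure level across stimuli.
#'
#' @param audio A [waveform()].
#' @param target_level Amplitude ratio in (0, 1\] or dBFS <= 0. Default -3 dBFS.
#' @return A [waveform()] with the requested peak.
#' @export
normalize_peak <- function(audio, target_level = -3) {
  stopifnot(inherits(audio, "waveform"))
  peak <- max(abs(audio$samples))
  if (peak == 0) abort_emogate("cannot normalize silent audio (zero peak)")
  ratio <- if (target_level > 0) target_level else 10^(target_level / 20)
  if (ratio > 1 + 1e-12) {
    abort_emogate("target peak above full scale (ratio > 1)")
  }
  waveform(audio$samples * (ratio / peak), audio$sample_rate_hz)
}

#' Plan the gated trials of one stimulus item
#'
#' One trial per finite gate plus, when the spec includes it, a full-duration
#' trial whose playable duration is the item's own length. Items too brief
#' for the requested gating are rejected by name.
#'
#' @param item One-row data frame (or list) with at least `item_id` and
#'   `full_duration_ms`; `event_type`, `language`, `emotion` are carried
#'   through when present.
#' @param spec A [gate_spec()].
#' @return Tibble of trial definitions: `item_id`, `gate`,
#'   `playable_duration_ms`, plus carried item fields.
#' @export
plan_gates <- function(item, spec = gate_spec()) {
  item <- as.list(item)
  fin <- spec$finite_gates_ms
  if (length(fin) > 0 && item$full_duration_ms <= max(fin)) {
    abort_emogate(paste0(
      "item '", item$item_id, "' (", item$full_duration_ms,
      " ms) is too brief for gating at ", max(fin), " ms"
    ))
  }
  labs <- gate_labels(spec)
  out <- tibble::tibble(
    item_id = item$item_id,
    gate = labs,
    playable_duration_ms = gate_duration_ms(labs, spec, item$full_duration_ms)
  )
  for (f in c("event_type", "language", "emotion")) {
    if (!is.null(item[[f]])) out[[f]] <- item[[f]]
  }
  out
}

#' Enumerate the full gated trial inventory
#'
#' Concatenates [plan_gates()] over an item table; the inventory size is
#' number of items times number of gates (e.g. 50 vocalizations x 5 gates =
#' 250 trials, 144 utterances x 5 gates = 720 trials).
#'
#' @param items Item tibble (see [response_dataset()]).
#' @param spec A [gate_spec()].
#' @return Tibble of trial definitions.
#' @export
build_trial_inventory <- function(items, spec = gate_spec()) {
  items <- tibble::as_tibble(items)
  if (nrow(items) == 0) {
    return(tibble::tibble(item_id = character(), gate = character(),
                          playable_duration_ms = numeric()))
  }
  purrr::map_dfr(seq_len(nrow(items)), function(i) plan_gates(items[i, ], spec))
}

#' Build the blocked presentation schedule
#'
#' Trials are presented in blocks of strictly ascending gate duration,
#' always starting from the shortest gate; within each duration the two vocal
#' event types are never intermixed but form separate sub-blocks whose order
#' follows `order_policy` (counterbalancing across participants is handled by
#' calling this per participant with the appropriate policy). Item order
#' within a sub-block is a seed-determined permutation, which intermixes the
#' languages of speech trials. Practice trials are an annotation
#' (`n_practice`) prepended by the presentation software, not timing logic.
#'
#' @param trials Trial tibble from [build_trial_inventory()]; must carry
#'   `event_type`.
#' @param order_policy `"speech_first"` or `"vocal_first"` within each gate.
#' @param practice_per_block Number of practice trials announced per block.
#' @param seed Integer seed controlling the within-block permutations.
#' @param spec A [gate_spec()].
#' @return Tibble with one row per sub-block: `block`, `gate`, `event_type`,
#'   `n_practice`, and a `trials` list-column of ordered trial tibbles.
#' @export
build_block_schedule <- function(trials,
                                 order_policy = c("speech_first", "vocal_first"),
                                 practice_per_block = 5, seed,
                                 spec = gate_spec()) {
  order_policy <- match.arg(order_policy)
  trials <- tibble::as_tibble(trials)
  if (nrow(trials) == 0) abort_emogate("no trials to schedule")
  if (!"event_type" %in% names(trials)) {
    abort_emogate("trials must carry an event_type column for scheduling")
  }
  gates <- intersect(gate_labels(spec), unique(trials$gate))
  types <- if (order_policy == "speech_first") {
    c("prosody", "vocalization")
  } else {
    c("vocalization", "prosody")
  }
  types <- intersect(types, unique(trials$event_type))
  withr::with_seed(seed, {
    blocks <- list()
    b <- 0L
    for (g in gates) {
      for (ty in types) {
        sub <- trials[trials$gate == g & trials$event_type == ty, ]
        if (nrow(sub) == 0) next
        b <- b + 1L
        sub <- sub[sample.int(nrow(sub)), ]
        sub$position <- seq_len(nrow(sub))
        blocks[[b]] <- tibble::tibble(
          block = b, gate = g, event_type = ty,
          n_practice = as.integer(practice_per_block),
          trials = list(sub)
        )
      }
    }
    dplyr::bind_rows(blocks)
  })
}
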