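#' Canonical label sets
#'
#' The forced-choice task offers exactly five response options; stimulus
#' categories additionally distinguish two positive vocalization subtypes
#' (amusement/laughter vs. pleasure/contentment sounds) that share the single
#' "happiness" response label on screen.
#'
#' @format Character vectors of lower-case tokens.
#' @name labels
NULL

#' @rdname labels
#' @export
response_labels <- function() {
  c("anger", "happiness", "fear", "sadness", "neutral")
}

#' @rdname labels
#' @export
emotion_labels <- function() {
  c("anger", "fear", "sadness", "happiness",
    "happiness_amusement", "happiness_pleasure")
}

#' @rdname labels
#' @export
language_labels <- function() {
  c("arabic", "mandarin", "english", "none")
}

#' @rdname labels
#' @export
event_type_labels <- function() {
  c("vocalization", "prosody")
}

#' Map a stimulus emotion category to its target response label
#'
#' Both happiness subtypes map onto the "happiness" response option; all other
#' categories are their own target.
#'
#' @param emotion Character vector of stimulus emotion categories.
#' @return Character vector of response labels.
#' @export
#' @examples
#' target_response(c("anger", "happiness_amusement"))
target_response <- function(emotion) {
  ifelse(startsWith(emotion, "happiness"), "happiness", emotion)
}
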