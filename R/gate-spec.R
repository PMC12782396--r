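#' Gate specification
#'
#' A gating design truncates every stimulus at a fixed set of durations
#' measured from acoustic onset, optionally followed by the full, unedited
#' expression. The default reproduces the G200/G400/G500/G600/GFull design.
#'
#' @param finite_gates_ms Strictly increasing positive durations (ms).
#' @param include_full Include the full-duration gate (GFULL)?
#' @return An object of class `gate_spec`.
#' @export
#' @examples
#' gate_spec()
#' gate_spec(c(100, 300), include_full = FALSE)
gate_spec <- function(finite_gates_ms = c(200, 400, 500, 600),
                      include_full = TRUE) {
  if (length(finite_gates_ms) < 1 && !include_full) {
    abort_emogate("a gate spec needs at least one gate")
  }
  if (any(finite_gates_ms <= 0)) {
    abort_emogate("finite gate durations must be positive")
  }
  if (is.unsorted(finite_gates_ms, strictly = TRUE)) {
    abort_emogate("finite gate durations must be strictly increasing")
  }
  structure(
    list(finite_gates_ms = as.numeric(finite_gates_ms),
         include_full = isTRUE(include_full)),
    class = "gate_spec"
  )
}

#' Gate labels of a spec, in ascending duration order
#'
#' Finite gates are labelled `G<ms>`; the full-duration gate is `GFULL`.
#'
#' @param spec A [gate_spec()].
#' @return Character vector of gate labels.
#' @export
gate_labels <- function(spec) {
  stopifnot(inherits(spec, "gate_spec"))
  lab <- paste0("G", format(spec$finite_gates_ms, scientific = FALSE, trim = TRUE))
  if (spec$include_full) lab <- c(lab, "GFULL")
  lab
}

#' Playable duration for gate labels
#'
#' @param gate Character vector of gate labels.
#' @param spec A [gate_spec()].
#' @param full_duration_ms Full stimulus durations, recycled against `gate`;
#'   used for `GFULL`.
#' @return Numeric durations in milliseconds.
#' @export
gate_duration_ms <- function(gate, spec, full_duration_ms = NA_real_) {
  stopifnot(inherits(spec, "gate_spec"))
  bad <- setdiff(unique(gate), gate_labels(spec))
  if (length(bad) > 0) {
    abort_emogate(paste0("unknown gate label(s): ", paste(bad, collapse = ", ")))
  }
  ms <- suppressWarnings(as.numeric(sub("^G", "", gate)))
  ifelse(gate == "GFULL", as.numeric(full_duration_ms), ms)
}

# integer index of each gate label in ascending-duration order
gate_index <- function(gate, spec) {
  match(gate, gate_labels(spec))
}

#' @export
print.gate_spec <- function(x, ...) {
  cat("<gate_spec> ", paste(gate_labels(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
format.gate_spec <- function(x, ...) paste(gate_labels(x), collapse = ",")
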