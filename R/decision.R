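#' Majority vote over a short label window
#'
#' Returns the modal label of `window` (chronological order, oldest first).
#' On ties, the previous voted output is kept if it is among the tied
#' labels; otherwise the tied label occurring earliest in the window wins.
#' Retaining the previous output on ties minimizes chatter in the smoothed
#' command stream.
#'
#' @param window Character vector of labels (typically the last 5).
#' @param previous_output Previous voted label, or `NULL`.
#' @return A single label.
#' @export
#' @examples
#' majority_vote(c("U", "U", "R", "U", "U"))                  # "U"
#' majority_vote(c("U", "U", "R", "R", "F-S"), "U")           # tie -> "U"
majority_vote <- function(window, previous_output = NULL) {
  if (length(window) == 0) abort("`window` must be nonempty.")
  counts <- table(window)
  tied <- names(counts)[counts == max(counts)]
  if (length(tied) == 1) return(tied)
  if (!is.null(previous_output) && previous_output %in% tied) {
    return(previous_output)
  }
  # earliest first occurrence in the window among the tied labels
  tied[which.min(match(tied, window))]
}

#' Smooth a classification stream by sliding majority-of-5
#'
#' Applies [majority_vote()] over a sliding window of the last `width`
#' labels: as each new recognition arrives the oldest one is discarded and
#' the vote re-run. The first `width - 1` outputs vote over the partial
#' window, so output length always equals input length.
#'
#' @param stream Character vector of raw per-window classifications.
#' @param width Voting window length. Default 5.
#' @return Character vector of voted labels, same length as `stream`.
#' @export
#' @examples
#' smooth_stream(c("U", "U", "R", "U", "U", "U"))
smooth_stream <- function(stream, width = 5) {
  n <- length(stream)
  if (n == 0) abort("`stream` must be nonempty.")
  labs <- unique(stream)
  if (length(labs) == 1) return(stream)
  code <- match(stream, labs)
  K <- length(labs)

  # windowed counts via per-label cumulative sums
  counts <- matrix(0L, n, K)
  for (k in seq_len(K)) {
    cs <- cumsum(code == k)
    counts[, k] <- cs - c(rep(0L, min(width, n)), cs[seq_len(max(0, n - width))])
  }
  mx <- do.call(pmax, as.data.frame(counts))
  n_tied <- rowSums(counts == mx)
  out_code <- max.col(counts, ties.method = "first")

  # resolve tied rows sequentially (they need the previous voted output)
  for (i in which(n_tied > 1)) {
    w <- code[max(1, i - width + 1):i]
    tied <- which(counts[i, ] == mx[i])
    prev <- if (i > 1) out_code[i - 1] else NA_integer_
    out_code[i] <- if (!is.na(prev) && prev %in% tied) {
      prev
    } else {
      tied[which.min(match(tied, w))]
    }
  }
  labs[out_code]
}

#' Fresh decision state for the command trigger
#'
#' @return A list of class `decision_state` tracking the current run of
#'   identical labels and whether the trigger is armed.
#' @export
new_decision_state <- function() {
  structure(list(run_label = NA_character_, run_length = 0L, armed = TRUE,
                 last_emitted = NA_character_),
            class = "decision_state")
}

#' Advance the command trigger by one voted label
#'
#' The trigger emits a movement command exactly once when five consecutive
#' identical non-rest labels have been seen; the run must break (a different
#' label arrive) before the same command can fire again, so a held posture
#' commands once. `RELAX` never emits: rest is a state, not an instruction.
#'
#' @param state A `decision_state` (see [new_decision_state()]).
#' @param label The next voted label.
#' @param required Run length required to trigger. Default 5.
#' @return A list with elements `state` (updated) and `command` (the label,
#'   or `NA_character_` when nothing fires).
#' @export
#' @examples
#' s <- new_decision_state()
#' for (lab in rep("U", 5)) {
#'   step <- trigger_step(s, lab)
#'   s <- step$state
#' }
#' step$command  # "U" fired on the 5th consecutive result
trigger_step <- function(state, label, required = 5) {
  if (!inherits(state, "decision_state")) {
    abort("`state` must come from new_decision_state().")
  }
  if (identical(label, state$run_label)) {
    state$run_length <- state$run_length + 1L
  } else {
    state$run_label <- label
    state$run_length <- 1L
    state$armed <- TRUE
  }
  command <- NA_character_
  if (state$armed && state$run_length >= required && label != "RELAX") {
    command <- label
    state$last_emitted <- label
    state$armed <- FALSE
  }
  list(state = state, command = command)
}

#' Run the command trigger over a whole voted stream
#'
#' @param stream Character vector of voted labels.
#' @param required Run length required to trigger. Default 5.
#' @return Character vector aligned with `stream`: the emitted command at
#'   the step it fires, `NA_character_` elsewhere.
#' @export
trigger_stream <- function(stream, required = 5) {
  state <- new_decision_state()
  out <- rep(NA_character_, length(stream))
  for (i in seq_along(stream)) {
    step <- trigger_step(state, stream[i], required)
    state <- step$state
    out[i] <- step$command
  }
  out
}

#' End-to-end online recognition of a recording
#'
#' Deploys a trained network on a recording the way the online controller
#' would: windowed feature extraction, projection onto the selected
#' features, per-window classification, majority-of-5 smoothing, and the
#' five-consecutive-identical command trigger.
#'
#' @param model A fitted `bpnn`.
#' @param recording An `emg_recording`.
#' @param feature_config A [feature_config()]; must match the one used in
#'   training.
#' @param selected Selected feature names (the model's inputs); defaults to
#'   the model's stored feature names.
#' @return A tibble with columns `window`, `raw`, `voted`, `command`
#'   (`NA` where no command fires).
#' @export
recognize_online <- function(model, recording,
                             feature_config = wristemg::feature_config(),
                             selected = model$feature_names) {
  feats <- extract_features(recording, feature_config)
  feats <- project_features(feats, selected)
  raw <- predict(model, feats)
  voted <- smooth_stream(raw)
  tibble(window = feats$window, raw = raw, voted = voted,
         command = trigger_stream(voted))
}
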