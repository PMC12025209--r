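#' Time-domain sEMG features
#'
#' The five time-domain features used throughout the pipeline, computed on a
#' single window of samples `x_1..x_N`:
#'
#' * `mav(x)` — mean absolute value, `(1/N) * sum |x_i|`.
#' * `rms(x)` — root mean square, `sqrt((1/N) * sum x_i^2)`.
#' * `var_pop(x)` — population variance, `(1/N) * sum (x_i - mean)^2`
#'   (note the `1/N` normalization, not the sample `1/(N-1)`).
#' * `zc(x, threshold)` — thresholded zero-crossing rate: the fraction
#'   `(1/N) * sum_{i<N} [x_i * x_{i+1} < 0 and |x_i - x_{i+1}| > threshold]`.
#'   The threshold rejects crossings driven by low-amplitude noise.
#' * `wl(x)` — normalized waveform length, `(1/N) * sum |x_{i+1} - x_i|`.
#'
#' `zc` and `wl` keep the `1/N` normalization (many toolboxes report the raw
#' count/sum); this makes them rates independent of the window length.
#'
#' @param x Numeric vector of samples (nonempty; `zc` and `wl` need at least
#'   two samples).
#' @param threshold Nonnegative crossing threshold in signal units.
#' @return A single number.
#' @name td_features
#' @examples
#' mav(c(1, -2, 3))     # 2
#' rms(c(3, 4))         # sqrt(12.5)
#' var_pop(c(0, 2))     # 1
#' zc(c(1, -1, 1, -1), threshold = 0.5)  # 0.75
#' wl(c(0, 1, 0, 1))    # 0.75
NULL

#' @rdname td_features
#' @export
mav <- function(x) {
  if (length(x) == 0) abort("`x` must be nonempty.")
  mean(abs(x))
}

#' @rdname td_features
#' @export
rms <- function(x) {
  if (length(x) == 0) abort("`x` must be nonempty.")
  sqrt(mean(x^2))
}

#' @rdname td_features
#' @export
var_pop <- function(x) {
  if (length(x) == 0) abort("`x` must be nonempty.")
  mean((x - mean(x))^2)
}

#' @rdname td_features
#' @export
zc <- function(x, threshold = 0) {
  n <- length(x)
  if (n < 2) abort("`x` must have at least 2 samples.")
  if (threshold < 0) abort("`threshold` must be nonnegative.")
  a <- x[-n]
  b <- x[-1]
  sum(a * b < 0 & abs(a - b) > threshold) / n
}

#' @rdname td_features
#' @export
wl <- function(x) {
  n <- length(x)
  if (n < 2) abort("`x` must have at least 2 samples.")
  sum(abs(diff(x))) / n
}

#' Feature extraction configuration
#'
#' @param window_length Analysis window in seconds. Default 0.2 s (200 ms),
#'   standard practice in myoelectric control.
#' @param window_step Hop between windows in seconds, `0 < step <= window`.
#'   Default 0.05 s.
#' @param zc_threshold Zero-crossing threshold. Either `NULL` (default): per
#'   window and channel, `0.01 *` that window's RMS, which keeps the
#'   crossing count gain-invariant; or a single nonnegative absolute value
#'   in signal units.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(window_length = 0.2, window_step = 0.05,
                           zc_threshold = NULL) {
  if (window_length <= 0) abort("`window_length` must be positive.")
  if (window_step <= 0 || window_step > window_length) {
    abort("`window_step` must satisfy 0 < step <= window_length.")
  }
  if (!is.null(zc_threshold)) {
    assert_scalar_number(zc_threshold, "zc_threshold", min = 0)
  }
  structure(list(window_length = window_length, window_step = window_step,
                 zc_threshold = zc_threshold),
            class = "feature_config")
}

feature_stats <- c("MAV", "RMS", "VAR", "ZC", "WL")

#' Names of the feature columns in a feature tibble
#'
#' Channel-major order: `ch1_MAV, ch1_RMS, ch1_VAR, ch1_ZC, ch1_WL, ch2_MAV,
#' ...` — 40 names for 8 channels.
#'
#' @param n_channels Number of channels. Default 8.
#' @return Character vector of column names.
#' @export
feature_names <- function(n_channels = 8) {
  as.vector(t(outer(paste0("ch", seq_len(n_channels), "_"), feature_stats,
                    paste0)))
}

#' Extract windowed time-domain features from a recording
#'
#' Slides a window of `window_length` seconds in hops of `window_step`
#' seconds across the recording and computes all five time-domain features
#' (see [td_features]) on every channel in every window. An 8-channel
#' recording yields 40 feature columns. A recording carrying a movement
#' annotation propagates it to every window's `label`.
#'
#' @param recording An `emg_recording` (see [generate_recording()]), or any
#'   data frame with a `t` column, channel columns `ch1..chK` and a
#'   `sampling_rate` attribute.
#' @param config A [feature_config()].
#' @return A tibble with columns `window` (1-based index), `t_center`
#'   (window center, seconds), `label`, and the feature columns of
#'   [feature_names()], in channel-major order.
#' @export
#' @examples
#' rec <- generate_recording("E-L", config = generator_config(duration = 1))
#' feats <- extract_features(rec)
#' dim(feats)  # 17 windows x (3 + 40) columns
extract_features <- function(recording, config = feature_config()) {
  fs <- attr(recording, "sampling_rate")
  if (is.null(fs)) abort("`recording` must carry a `sampling_rate` attribute.")
  chans <- grep("^ch[0-9]+$", names(recording), value = TRUE)
  chans <- chans[order(as.integer(sub("ch", "", chans)))]
  if (length(chans) == 0) abort("`recording` has no channel columns (ch1..).")
  len <- round(config$window_length * fs)
  step <- round(config$window_step * fs)
  n <- nrow(recording)
  if (n < len) abort("Recording is shorter than one analysis window.")
  starts <- seq(1, n - len + 1, by = step)
  sig <- as.matrix(recording[chans])
  lab <- attr(recording, "movement")
  if (is.null(lab)) lab <- NA_character_

  rows <- purrr::map(starts, function(s) {
    win <- sig[s:(s + len - 1), , drop = FALSE]
    vals <- purrr::map(seq_along(chans), function(c) {
      x <- win[, c]
      th <- config$zc_threshold
      if (is.null(th)) th <- 0.01 * rms(x)
      c(mav(x), rms(x), var_pop(x), zc(x, th), wl(x))
    })
    unlist(vals)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- feature_names(length(chans))
  out <- tibble(window = seq_along(starts),
                t_center = (starts - 1 + (len - 1) / 2) / fs,
                label = lab)
  dplyr::bind_cols(out, as_tibble(m))
}

#' Columns of a feature tibble that hold feature values
#'
#' @param features A feature tibble.
#' @return Character vector of feature column names present, channel-major.
#' @export
feature_cols <- function(features) {
  intersect(feature_names(64), names(features))
}
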