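#' Wrist movement labels
#'
#' The seven wrist states recognized by the pipeline: flexion over a small or
#' large range (`F-S`, `F-L`), extension over a small or large range (`E-S`,
#' `E-L`), radial deviation (`R`), ulnar deviation (`U`), and the resting
#' state (`RELAX`). `RELAX` is the designated rest class: it never triggers a
#' movement command.
#'
#' @return Character vector of the seven labels, in canonical order.
#' @export
#' @examples
#' movement_labels()
movement_labels <- function() {
  c("F-S", "F-L", "E-S", "E-L", "R", "U", "RELAX")
}

#' Default movement-by-channel activation profile
#'
#' Amplitude factors mimicking channel-specific muscle bursts under an
#' 8-electrode forearm armband: each non-rest movement has two dominant
#' channels (factor 1.0), two moderate (0.5) and four weak (0.15); the rest
#' class sits at 0.05 on every channel. Rows are pairwise distinct, so the
#' seven classes are separable in expected-amplitude space by construction.
#'
#' @return A 7 x 8 numeric matrix with movement rownames and `ch1`..`ch8`
#'   colnames.
#' @export
default_activation_profile <- function() {
  moves <- movement_labels()
  prof <- matrix(0.15, nrow = 7, ncol = 8,
                 dimnames = list(moves, paste0("ch", 1:8)))
  dominant <- list(`F-S` = c(1, 2), `F-L` = c(2, 3), `E-S` = c(4, 5),
                   `E-L` = c(5, 6), `R` = c(7, 8), `U` = c(8, 1))
  moderate <- list(`F-S` = c(3, 4), `F-L` = c(4, 5), `E-S` = c(6, 7),
                   `E-L` = c(7, 8), `R` = c(1, 2), `U` = c(2, 3))
  for (m in names(dominant)) {
    prof[m, dominant[[m]]] <- 1.0
    prof[m, moderate[[m]]] <- 0.5
  }
  prof["RELAX", ] <- 0.05
  prof
}

#' Configuration for the synthetic sEMG generator
#'
#' Bundles everything the generator needs to emulate an 8-channel sEMG
#' armband: sampling rate, recording duration, RNG seed, the movement-by-
#' channel activation profile, the amplitude model (base amplitude plus a
#' linear load term), and the passband of the noise carrier.
#'
#' The signal model is zero-mean band-limited Gaussian noise whose expected
#' mean absolute value (MAV) on channel `c` during movement `m` under load
#' `L` newtons is `profile[m, c] * (base_amplitude + load_gain * L)`. Signal
#' units are arbitrary but consistent across the package.
#'
#' @param sampling_rate Sampling rate in Hz. Default 1000.
#' @param duration Recording length in seconds. Default 30, the length of one
#'   movement set in the acquisition protocol the generator emulates.
#' @param seed Integer RNG seed.
#' @param activation_profile 7 x 8 nonnegative matrix of amplitude factors
#'   (movements in the order of [movement_labels()] by channels). The rest
#'   row must be elementwise smaller than every other row, and rows must be
#'   pairwise distinct.
#' @param base_amplitude Expected-MAV scale at zero load, signal units.
#' @param load_gain Expected-MAV increase per newton of load, signal units/N.
#' @param band Two-element passband (low, high) in Hz for the noise carrier;
#'   default 20-450 Hz, the band holding most surface-EMG energy.
#' @return A list of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(duration = 2, seed = 42)
#' rec <- generate_recording("U", load = 10, config = cfg)
generator_config <- function(sampling_rate = 1000, duration = 30, seed = 1,
                             activation_profile = default_activation_profile(),
                             base_amplitude = 1, load_gain = 0.05,
                             band = c(20, 450)) {
  assert_scalar_number(sampling_rate, "sampling_rate", min = 1)
  assert_scalar_number(duration, "duration")
  if (duration <= 0) abort("`duration` must be positive.")
  assert_scalar_number(load_gain, "load_gain", min = 0)
  assert_scalar_number(base_amplitude, "base_amplitude", min = 0)
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2] ||
      band[2] >= sampling_rate / 2) {
    abort("`band` must satisfy 0 < low < high < sampling_rate / 2.")
  }
  prof <- as.matrix(activation_profile)
  if (!all(dim(prof) == c(7, 8))) {
    abort("`activation_profile` must be a 7 x 8 matrix (movements x channels).")
  }
  if (is.null(rownames(prof))) rownames(prof) <- movement_labels()
  if (any(prof < 0)) abort("`activation_profile` must be nonnegative.")
  others <- setdiff(rownames(prof), "RELAX")
  if (!all(apply(prof[others, , drop = FALSE], 1,
                 function(r) all(prof["RELAX", ] < r)))) {
    abort("The RELAX row of `activation_profile` must be strictly below every other row.")
  }
  if (anyDuplicated(apply(prof, 1, paste, collapse = ","))) {
    abort("Rows of `activation_profile` must be pairwise distinct.")
  }
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 seed = as.integer(seed), activation_profile = prof,
                 base_amplitude = base_amplitude, load_gain = load_gain,
                 band = band),
            class = "generator_config")
}

# Band-limited unit-variance Gaussian carrier, one column per channel.
band_limited_noise <- function(n, n_channels, sampling_rate, band) {
  bf <- signal::butter(2, band / (sampling_rate / 2), type = "pass")
  x <- matrix(rnorm(n * n_channels), nrow = n, ncol = n_channels)
  apply(x, 2, function(col) signal::filtfilt(bf, col))
}

#' Generate one synthetic sEMG recording
#'
#' Produces an 8-channel recording of band-limited, zero-mean Gaussian sEMG
#' whose per-channel expected MAV follows the configured amplitude model.
#' For zero-mean Gaussian noise of standard deviation `s`, `E[MAV] =
#' s * sqrt(2/pi)`; each channel is scaled so the configured expectation
#' holds. Identical `(movement, load, seed)` give bit-identical output.
#'
#' @param movement One of [movement_labels()].
#' @param load External load in newtons (>= 0). Default 0.
#' @param config A [generator_config()].
#' @return A tibble of class `emg_recording` with columns `t` (seconds) and
#'   `ch1`..`ch8`, and attributes `sampling_rate`, `movement` and `load`.
#' @export
#' @examples
#' rec <- generate_recording("F-L", load = 5,
#'                           config = generator_config(duration = 1))
#' colMeans(abs(rec[paste0("ch", 1:8)]))
generate_recording <- function(movement, load = 0,
                               config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  movement <- match.arg(movement, movement_labels())
  assert_scalar_number(load, "load", min = 0)
  n <- round(config$duration * config$sampling_rate)
  target_mav <- config$activation_profile[movement, ] *
    (config$base_amplitude + config$load_gain * load)
  seed <- derive_seed(config$seed, 131 * (match(movement, movement_labels()) - 1))
  x <- with_seed(seed, band_limited_noise(n, 8, config$sampling_rate,
                                          config$band))
  sds <- apply(x, 2, sd)
  target_sd <- target_mav * sqrt(pi / 2)
  x <- sweep(x, 2, ifelse(sds > 0, target_sd / sds, 0), "*")
  colnames(x) <- paste0("ch", 1:8)
  out <- tibble(t = (seq_len(n) - 1) / config$sampling_rate)
  out <- dplyr::bind_cols(out, as_tibble(x))
  new_emg_recording(out, sampling_rate = config$sampling_rate,
                    movement = movement, load = load)
}

new_emg_recording <- function(df, sampling_rate, movement = NA_character_,
                              load = NA_real_) {
  structure(df,
            sampling_rate = sampling_rate, movement = movement, load = load,
            class = c("emg_recording", class(tibble())))
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x %d channels @ %g Hz",
              nrow(x), sum(grepl("^ch", names(x))), attr(x, "sampling_rate")))
  mv <- attr(x, "movement")
  if (!is.na(mv)) cat(sprintf("  movement=%s load=%g N", mv, attr(x, "load")))
  cat("\n")
  NextMethod()
}

#' Generate a balanced labeled dataset of recordings
#'
#' Repeats every movement `reps_per_movement` times at every load, each
#' repetition with its own derived seed so no two recordings share a noise
#' realization, while the whole dataset is deterministic under the
#' configuration seed.
#'
#' @param reps_per_movement Repetitions per (movement, load) cell, >= 1.
#' @param loads Numeric vector of loads in newtons. Default 0.
#' @param config A [generator_config()].
#' @return A tibble with columns `movement`, `load`, `rep` and a `recording`
#'   list-column of `emg_recording` objects.
#' @export
generate_dataset <- function(reps_per_movement, loads = 0,
                             config = generator_config()) {
  if (reps_per_movement < 1) abort("`reps_per_movement` must be >= 1.")
  grid <- tidyr::expand_grid(movement = movement_labels(), load = loads,
                             rep = seq_len(reps_per_movement))
  grid %>%
    mutate(recording = purrr::pmap(
      list(.data$movement, .data$load, seq_len(nrow(grid))),
      function(mv, ld, i) {
        cfg <- config
        cfg$seed <- derive_seed(config$seed, 10007 * i)
        generate_recording(mv, load = ld, config = cfg)
      }))
}

#' Generate a labeled feature dataset
#'
#' Convenience wrapper producing a fixed number of feature windows per
#' movement: one recording per movement just long enough to yield
#' `windows_per_movement` sliding windows, passed through
#' [extract_features()].
#'
#' @param windows_per_movement Windows per class. Default 60, one per
#'   repetition of a 60-repetition acquisition set.
#' @param loads Single load in newtons applied to every movement. Default 0.
#' @param config A [generator_config()]; its `duration` is overridden.
#' @param feature_config A [feature_config()].
#' @return A labeled feature tibble (see [extract_features()]).
#' @export
generate_feature_dataset <- function(windows_per_movement = 60, loads = 0,
                                     config = generator_config(),
                                     feature_config = wristemg::feature_config()) {
  dur <- (windows_per_movement - 1) * feature_config$window_step +
    feature_config$window_length
  purrr::map_dfr(seq_along(movement_labels()), function(i) {
    cfg <- config
    cfg$duration <- dur
    cfg$seed <- derive_seed(config$seed, 7717 * i)
    rec <- generate_recording(movement_labels()[i], load = loads, config = cfg)
    extract_features(rec, feature_config)
  })
}

#' Corrupt a ground-truth label stream with iid frame errors
#'
#' Null model for studying decision smoothing: each frame keeps its true
#' label with probability `frame_accuracy`, otherwise it is replaced by a
#' label drawn uniformly from the other six movement labels.
#'
#' @param truth Character vector of true labels (subset of
#'   [movement_labels()]).
#' @param frame_accuracy Per-frame probability of keeping the true label.
#' @param seed Integer RNG seed.
#' @return Character vector the same length as `truth`.
#' @export
#' @examples
#' generate_label_stream(rep("U", 10), frame_accuracy = 0.5, seed = 1)
generate_label_stream <- function(truth, frame_accuracy, seed = 1) {
  if (length(truth) == 0) abort("`truth` must be a nonempty label vector.")
  if (frame_accuracy < 0 || frame_accuracy > 1) {
    abort("`frame_accuracy` must be in [0, 1].")
  }
  labels <- movement_labels()
  if (!all(truth %in% labels)) abort("`truth` contains unknown labels.")
  with_seed(seed, {
    n <- length(truth)
    keep <- runif(n) < frame_accuracy
    out <- truth
    if (any(!keep)) {
      idx <- which(!keep)
      # draw uniformly from the 6 labels other than the true one
      pick <- sample.int(6L, length(idx), replace = TRUE)
      out[idx] <- vapply(seq_along(idx), function(j) {
        setdiff(labels, truth[idx[j]])[pick[j]]
      }, character(1))
    }
    out
  })
}

#' Generate a minimum-jerk wrist kinematic trace
#'
#' Produces a smooth out-and-back flexion/extension angle trajectory: the
#' wrist moves from rest to `peak_angle` and back along minimum-jerk
#' profiles, then holds at rest for the remainder of `duration`. In `fast`
#' mode the movement occupies half the time it does in `slow` mode, which
#' quadruples the peak angular acceleration. The angular acceleration is
#' returned analytically (not by differencing).
#'
#' @param peak_angle Peak flexion/extension angle in radians.
#' @param duration Trace length in seconds (> 0); `slow` movements occupy the
#'   whole trace, `fast` ones its first half.
#' @param speed_mode `"slow"` or `"fast"`.
#' @param sampling_rate Hz. Default 1000.
#' @return A tibble with columns `time` (s), `angle` (rad) and
#'   `angular_acceleration` (rad/s^2).
#' @export
#' @examples
#' kin <- generate_kinematics(pi / 4, duration = 2, speed_mode = "slow",
#'                            sampling_rate = 200)
#' range(kin$angle)
generate_kinematics <- function(peak_angle, duration,
                                speed_mode = c("slow", "fast"),
                                sampling_rate = 1000) {
  speed_mode <- match.arg(speed_mode)
  if (duration <= 0) abort("`duration` must be positive.")
  t_move <- if (speed_mode == "fast") duration / 2 else duration
  half <- t_move / 2
  tt <- seq(0, duration, by = 1 / sampling_rate)
  # minimum-jerk position s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5 on [0, 1]
  pos <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  acc <- function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3
  angle <- numeric(length(tt))
  aacc <- numeric(length(tt))
  up <- tt <= half
  dn <- tt > half & tt <= t_move
  tau_up <- tt[up] / half
  tau_dn <- (tt[dn] - half) / half
  angle[up] <- peak_angle * pos(tau_up)
  aacc[up] <- peak_angle * acc(tau_up) / half^2
  angle[dn] <- peak_angle * (1 - pos(tau_dn))
  aacc[dn] <- -peak_angle * acc(tau_dn) / half^2
  tibble(time = tt, angle = angle, angular_acceleration = aacc)
}
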