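#' Construct a static MAV-to-force model
#'
#' The static model is affine: `force_N = slope * MAV + intercept`, one
#' model per movement direction (F, E, R, U).
#'
#' @param movement Movement direction label.
#' @param slope Newtons per MAV signal unit.
#' @param intercept Newtons.
#' @return An object of class `static_force_model`.
#' @export
static_force_model <- function(movement, slope, intercept) {
  assert_scalar_number(slope, "slope")
  assert_scalar_number(intercept, "intercept")
  structure(list(movement = movement, slope = slope, intercept = intercept),
            class = "static_force_model")
}

#' @export
print.static_force_model <- function(x, ...) {
  cat(sprintf("<static_force_model> %s: force_N = %.4g * MAV + %.4g\n",
              x$movement, x$slope, x$intercept))
  invisible(x)
}

#' @export
tidy.static_force_model <- function(x, ...) {
  tibble(movement = x$movement,
         term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept))
}

#' Reference static force models
#'
#' The calibrated coefficient set for the four movement directions, from a
#' graded-load experiment (loads of 5 to 50 N in 5 N steps, whole-set MAVs
#' averaged over three repetitions, ordinary least squares):
#' flexion `1.021 * MAV + 3.615`, extension `1.125 * MAV + 3.410`, radial
#' deviation `0.783 * MAV + 1.765`, ulnar deviation `0.459 * MAV + 4.863`.
#' Used as a fixture in examples and tests; fit your own with
#' [fit_static_model()].
#'
#' @param movement If given, return the single [static_force_model()] for
#'   that direction (`"F"`, `"E"`, `"R"` or `"U"`); otherwise a tibble of
#'   all four.
#' @return A tibble (`movement`, `slope`, `intercept`) or one
#'   `static_force_model`.
#' @export
#' @examples
#' predict_static_force(reference_static_models("U"), 0)  # 4.863
reference_static_models <- function(movement = NULL) {
  tab <- tibble(movement = c("F", "E", "R", "U"),
                slope = c(1.021, 1.125, 0.783, 0.459),
                intercept = c(3.615, 3.410, 1.765, 4.863))
  if (is.null(movement)) return(tab)
  row <- tab[tab$movement == match.arg(movement, tab$movement), ]
  static_force_model(row$movement, row$slope, row$intercept)
}

#' Fit a static force model from a load-trial table
#'
#' Averages the MAV over repetitions within each (movement, load) cell and
#' regresses load (newtons, response) on mean MAV (predictor) by ordinary
#' least squares, yielding the affine MAV-to-force map.
#'
#' @param table Load-trial tibble with columns `movement`, `load`, `rep`,
#'   `mav` (one row per repetition).
#' @param movement Which movement's rows to fit.
#' @return A `static_force_model` with `r_squared` and `n_loads` attached.
#' @export
fit_static_model <- function(table, movement) {
  need <- c("movement", "load", "mav")
  if (!all(need %in% names(table))) {
    abort("`table` needs columns movement, load, mav (and optionally rep).")
  }
  rows <- table[table$movement == movement, ]
  agg <- rows %>%
    group_by(.data$load) %>%
    summarise(mav = mean(.data$mav), .groups = "drop")
  if (nrow(agg) < 2) abort("Need at least 2 distinct loads to fit.")
  if (sd(agg$mav) == 0) abort("All MAVs identical; fit is singular.")
  fit <- lm(load ~ mav, data = agg)
  out <- static_force_model(movement, unname(coef(fit)[2]),
                            unname(coef(fit)[1]))
  out$r_squared <- 1 - sum(fit$residuals^2) / sum((agg$load - mean(agg$load))^2)
  out$n_loads <- nrow(agg)
  out
}

#' Predict force from MAV with a static model
#'
#' @param model A `static_force_model`.
#' @param mav MAV value(s), signal units (>= 0).
#' @return Force in newtons, same length as `mav`.
#' @export
predict_static_force <- function(model, mav) {
  if (!inherits(model, "static_force_model")) {
    abort("`model` must be a static_force_model.")
  }
  if (any(mav < 0)) abort("`mav` must be nonnegative.")
  model$slope * mav + model$intercept
}

#' Dynamic muscle-force trace
#'
#' Total dynamic force during a loaded wrist movement:
#' `F(t) = F0 + m * g + m * r * beta_ddot(t)` — a no-load baseline, the
#' gravity of the held weight, and the inertial term of the weight swinging
#' on the lever arm `r` from the wrist rotation center.
#'
#' @param kinematics A kinematic tibble with an `angular_acceleration`
#'   column (rad/s^2, e.g. from [generate_kinematics()]), or a bare numeric
#'   vector of angular accelerations.
#' @param f0 No-load force estimate, newtons.
#' @param mass Mass of the held weight, kg (>= 0). For a weight stated as a
#'   force `G` newtons, `mass = G / gravity`.
#' @param lever_arm Wrist-to-weight lever arm, meters. Default 0.07 (70 mm).
#' @param gravity m/s^2. Default 9.81.
#' @return If `kinematics` is a data frame, the tibble with a `force`
#'   column appended; otherwise a numeric force vector.
#' @export
#' @examples
#' dynamic_force(10, f0 = 2, mass = 10 / 9.81)  # 2 + 10 + 0.7136 N
dynamic_force <- function(kinematics, f0, mass, lever_arm = 0.07,
                          gravity = 9.81) {
  if (mass < 0) abort("`mass` must be nonnegative.")
  beta_ddot <- if (is.data.frame(kinematics)) {
    kinematics$angular_acceleration
  } else {
    kinematics
  }
  if (is.null(beta_ddot)) abort("`kinematics` lacks an angular_acceleration column.")
  force <- f0 + mass * gravity + mass * lever_arm * beta_ddot
  if (is.data.frame(kinematics)) {
    return(mutate(as_tibble(kinematics), force = force))
  }
  force
}

#' Estimate a force trace from a recording's MAV
#'
#' Slides a window over the recording, computes the mean MAV across
#' channels per window, and maps it through a static force model, giving an
#' estimated force trace aligned to window centers.
#'
#' @param recording An `emg_recording`.
#' @param model A `static_force_model`.
#' @param window Window length in seconds. Default 1.
#' @param step Hop in seconds. Default `window / 4`.
#' @param channels Channel columns to average; default all present.
#' @return A tibble with columns `t` (window center, s), `mav`, `force`
#'   (N).
#' @export
estimate_force <- function(recording, model, window = 1, step = window / 4,
                           channels = NULL) {
  fs <- attr(recording, "sampling_rate")
  if (is.null(fs)) abort("`recording` must carry a `sampling_rate` attribute.")
  if (is.null(channels)) {
    channels <- grep("^ch[0-9]+$", names(recording), value = TRUE)
  }
  len <- round(window * fs)
  hop <- max(1, round(step * fs))
  n <- nrow(recording)
  if (n < len) abort("Recording is shorter than one window.")
  starts <- seq(1, n - len + 1, by = hop)
  sig <- as.matrix(recording[channels])
  mavs <- vapply(starts, function(s) {
    mean(abs(sig[s:(s + len - 1), , drop = FALSE]))
  }, numeric(1))
  tibble(t = (starts - 1 + (len - 1) / 2) / fs, mav = mavs,
         force = predict_static_force(model, mavs))
}

#' Root mean squared error between two force traces
#'
#' @param estimated,reference Equal-length numeric traces (newtons).
#' @return RMSE in newtons.
#' @export
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 4))  # sqrt(1/3)
rmse <- function(estimated, reference) {
  if (length(estimated) != length(reference)) {
    abort("`estimated` and `reference` must have equal length.")
  }
  sqrt(mean((estimated - reference)^2))
}
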