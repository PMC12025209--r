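test_that("exact affine load-MAV data are recovered to machine precision", {
  tab <- tidyr::expand_grid(load = seq(5, 50, by = 5), rep = 1:3) %>%
    dplyr::mutate(movement = "E", mav = (load - 3.410) / 1.125)
  fit <- fit_static_model(tab, "E")
  expect_equal(fit$slope, 1.125, tolerance = 1e-12)
  expect_equal(fit$intercept, 3.410, tolerance = 1e-12)
})

test_that("shifting every MAV by c moves the intercept by -slope * c", {
  set.seed(9)
  tab <- tidyr::expand_grid(load = seq(5, 50, by = 5), rep = 1:3) %>%
    dplyr::mutate(movement = "R",
                  mav = (load - 1.765) / 0.783 + rnorm(dplyr::n(), sd = 0.3))
  f0 <- fit_static_model(tab, "R")
  shifted <- dplyr::mutate(tab, mav = mav + 2.5)
  f1 <- fit_static_model(shifted, "R")
  expect_equal(f1$slope, f0$slope)
  expect_equal(f1$intercept, f0$intercept - f0$slope * 2.5)
})

test_that("static fits recover the generating coefficients across seeds", {
  true_slope <- 1.125
  true_int <- 3.410
  errs <- vapply(1:100, function(s) {
    tab <- wristemg:::with_seed(s, {
      tidyr::expand_grid(load = seq(5, 50, by = 5), rep = 1:3) %>%
        dplyr::mutate(movement = "E",
                      mav = (load + rnorm(dplyr::n(), sd = 0.5) - true_int) /
                        true_slope)
    })
    fit <- fit_static_model(tab, "E")
    c(fit$slope - true_slope, fit$intercept - true_int)
  }, numeric(2))
  expect_lt(max(abs(errs[1, ])), 0.05)
  expect_lt(max(abs(errs[2, ])), 0.8)
})

test_that("reference static models predict their printed intercepts at MAV 0", {
  expect_identical(predict_static_force(reference_static_models("U"), 0), 4.863)
  expect_identical(predict_static_force(reference_static_models("E"), 0), 3.410)
  expect_equal(predict_static_force(reference_static_models("R"), 10), 9.595)
  expect_error(predict_static_force(reference_static_models("F"), -1),
               "nonnegative")
})

test_that("the dynamic model reduces to its static and unloaded limits", {
  kin <- generate_kinematics(0.5, 1, "slow", 200)
  # no mass: the trace is the no-load baseline everywhere
  expect_equal(dynamic_force(kin, f0 = 2, mass = 0)$force,
               rep(2, nrow(kin)))
  # no acceleration, 10 N weight: baseline plus exactly 10 N
  still <- rep(0, 50)
  expect_equal(dynamic_force(still, f0 = 2, mass = 10 / 9.81),
               rep(12, 50))
  # inertial term arithmetic: m r beta_ddot
  expect_equal(dynamic_force(10, f0 = 0, mass = 1.0194) - 1.0194 * 9.81,
               1.0194 * 0.07 * 10)
  expect_error(dynamic_force(still, f0 = 0, mass = -1), "nonnegative")
})

test_that("force traces from stationary recordings are flat", {
  rec <- generate_recording("F-L", load = 10,
                            config = generator_config(duration = 6, seed = 71))
  tr <- estimate_force(rec, reference_static_models("F"), window = 1)
  expect_lt((max(tr$force) - min(tr$force)) / mean(tr$force), 0.05)
  # doubling the amplitude raises the force by slope * delta MAV
  rec2 <- rec
  for (ch in paste0("ch", 1:8)) rec2[[ch]] <- rec2[[ch]] * 2
  attr(rec2, "sampling_rate") <- attr(rec, "sampling_rate")
  tr2 <- estimate_force(rec2, reference_static_models("F"), window = 1)
  expect_equal(tr2$force - tr$force, 1.021 * tr$mav, tolerance = 1e-10)
})

test_that("estimated force tracks the generator's programmed load ramp", {
  loads <- seq(5, 50, by = 5)
  cfg <- generator_config(duration = 2, seed = 81)
  mean_force <- vapply(loads, function(L) {
    rec <- generate_recording("R", load = L, config = cfg)
    mean(estimate_force(rec, reference_static_models("R"), window = 1)$force)
  }, numeric(1))
  expect_true(all(diff(mean_force) > 0))
})

test_that("end-to-end static calibration predicts held-out loads within 1 N", {
  cfg <- generator_config(duration = 4, seed = 91)
  whole_set_mav <- function(L, rep) {
    c2 <- cfg
    c2$seed <- wristemg:::derive_seed(cfg$seed, 37 * rep)
    rec <- generate_recording("R", load = L, config = c2)
    mean(abs(as.matrix(rec[paste0("ch", 1:8)])))
  }
  fit_loads <- c(5, 15, 25, 35, 45)
  tab <- tidyr::expand_grid(load = fit_loads, rep = 1:3) %>%
    dplyr::mutate(movement = "R",
                  mav = purrr::map2_dbl(load, rep, whole_set_mav))
  model <- fit_static_model(tab, "R")
  held_out <- c(10, 20, 30, 40, 50)
  pred <- vapply(held_out, function(L) {
    predict_static_force(model, whole_set_mav(L, 9))
  }, numeric(1))
  expect_lt(mean(abs(pred - held_out)), 1)
})

test_that("rmse matches its closed forms and a brute-force loop", {
  expect_equal(rmse(1:10, 1:10), 0)
  expect_equal(rmse(1:10 + 2.5, 1:10), 2.5)
  set.seed(3)
  a <- rnorm(100)
  b <- rnorm(100)
  s <- 0
  for (i in 1:100) s <- s + (a[i] - b[i])^2
  expect_equal(rmse(a, b), sqrt(s / 100))
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("degenerate force fits are rejected", {
  tab <- tibble::tibble(movement = "E", load = c(5, 10, 15), rep = 1,
                        mav = 2)
  expect_error(fit_static_model(tab, "E"), "singular")
  expect_error(fit_static_model(tab[1, ], "E"), "2 distinct loads")
})
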