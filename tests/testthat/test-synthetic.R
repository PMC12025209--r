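test_that("generated channels hit the configured expected MAV", {
  prof <- default_activation_profile()
  prof["R", ] <- 0.1  # uniform target row; RELAX row (0.05) stays below it
  cfg <- generator_config(duration = 10, seed = 11,
                          activation_profile = prof, base_amplitude = 1)
  rec <- generate_recording("R", load = 0, config = cfg)
  emp <- colMeans(abs(rec[paste0("ch", 1:8)]))
  expect_true(all(abs(emp - 0.1) / 0.1 < 0.05))
})

test_that("zero load gain makes MAV independent of load", {
  cfg <- generator_config(duration = 10, seed = 12, load_gain = 0)
  m0 <- colMeans(abs(generate_recording("U", 0, cfg)[paste0("ch", 1:8)]))
  m40 <- colMeans(abs(generate_recording("U", 40, cfg)[paste0("ch", 1:8)]))
  expect_true(all(abs(m40 - m0) / m0 < 0.03))
})

test_that("generation is bit-identical under a fixed seed, distinct across seeds", {
  cfg <- generator_config(duration = 0.5, seed = 42)
  a <- generate_recording("F-S", 10, cfg)
  b <- generate_recording("F-S", 10, cfg)
  expect_identical(a, b)
  cfg2 <- generator_config(duration = 0.5, seed = 43)
  c <- generate_recording("F-S", 10, cfg2)
  expect_false(isTRUE(all.equal(a$ch1, c$ch1)))
})

test_that("generate_dataset is balanced and realizations are disjoint", {
  ds <- generate_dataset(3, config = generator_config(duration = 0.3, seed = 5))
  expect_equal(nrow(ds), 21)
  expect_true(all(table(ds$movement) == 3))
  heads <- vapply(ds$recording, function(r) paste(head(r$ch1, 50),
                                                  collapse = ","), "")
  expect_equal(anyDuplicated(heads), 0L)
})

test_that("empirical MAV converges to the expectation as duration grows", {
  err_at <- function(dur) {
    cfg <- generator_config(duration = dur, seed = 21)
    rec <- generate_recording("RELAX", 0, cfg)
    mean(abs(colMeans(abs(rec[paste0("ch", 1:8)])) - 0.05)) / 0.05
  }
  errs <- vapply(c(0.5, 2, 8), err_at, numeric(1))
  expect_lt(errs[1], 0.10)
  expect_lt(errs[2], 0.05)
  expect_lt(errs[3], 0.02)
})

test_that("label-stream corruption has the configured agreement rate", {
  truth <- rep("F-L", 10)
  expect_identical(generate_label_stream(truth, 1, seed = 1), truth)
  none <- generate_label_stream(truth, 0, seed = 1)
  expect_true(all(none != truth))
  expect_true(all(none %in% movement_labels()))

  big <- rep(movement_labels()[1:6], each = 200)
  big <- rep(big, length.out = 1e5)
  corrupted <- generate_label_stream(big, 0.907, seed = 2)
  expect_lt(abs(mean(corrupted == big) - 0.907), 0.003)
  expect_error(generate_label_stream(character(0), 0.5), "nonempty")
})

test_that("kinematic traces are minimum-jerk out-and-back profiles", {
  fs <- 500
  slow <- generate_kinematics(0.6, duration = 2, speed_mode = "slow",
                              sampling_rate = fs)
  expect_equal(slow$angle[1], 0)
  expect_equal(slow$angle[nrow(slow)], 0, tolerance = 1e-10)
  expect_equal(max(slow$angle), 0.6, tolerance = 1e-6)
  # velocity returns to rest: integral of acceleration vanishes
  expect_lt(abs(sum(slow$angular_acceleration) / fs), 1e-3)
  # analytic acceleration agrees with the second difference of the angle
  num_acc <- diff(slow$angle, differences = 2) * fs^2
  expect_lt(max(abs(num_acc - slow$angular_acceleration[2:(nrow(slow) - 1)])),
            0.05 * max(abs(slow$angular_acceleration)))

  fast <- generate_kinematics(0.6, duration = 2, speed_mode = "fast",
                              sampling_rate = fs)
  ratio <- max(abs(fast$angular_acceleration)) /
    max(abs(slow$angular_acceleration))
  expect_equal(ratio, 4, tolerance = 0.02)
  expect_error(generate_kinematics(0.6, duration = -1), "positive")
})

test_that("classes are linearly separable in expected-MAV space", {
  cfg <- generator_config(duration = 0.2, seed = 33)
  feats <- generate_feature_dataset(15, config = cfg)
  mav_cols <- paste0("ch", 1:8, "_MAV")
  centroids <- cfg$activation_profile * cfg$base_amplitude
  assign_nearest <- function(v) {
    rownames(centroids)[which.min(rowSums(abs(sweep(centroids, 2, v))))]
  }
  pred <- apply(as.matrix(feats[mav_cols]), 1, assign_nearest)
  expect_gte(mean(pred == feats$label), 0.99)
})

test_that("degenerate generator configurations are rejected", {
  expect_error(generator_config(band = c(450, 20)), "band")
  expect_error(generator_config(band = c(20, 600)), "band")
  expect_error(generator_config(load_gain = -1), "load_gain")
  expect_error(generate_recording("U", load = -5), "load")
  prof <- default_activation_profile()
  prof["RELAX", 1] <- 2  # rest row no longer dominated
  expect_error(generator_config(activation_profile = prof), "RELAX")
})
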