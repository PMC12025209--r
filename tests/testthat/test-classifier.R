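test_that("hidden-layer sizing follows round(sqrt(m + n)) + a", {
  expect_identical(hidden_size(16, 7, 10), 15L)
  expect_identical(hidden_size(4, 5, 0), 3L)
  expect_identical(hidden_size(9, 7, 2), 6L)
  expect_error(hidden_size(16, 7, 11), "\\[0, 10\\]")
  expect_error(hidden_size(0, 7, 2), ">= 1")
})

test_that("forward outputs live on the probability simplex", {
  P <- forward_probs(shared_fit, shared_feats)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)))
  expect_true(all(P > 0 & P < 1))
  expect_identical(colnames(P), shared_fit$label_order)
})

test_that("zero weights give uniform class probabilities and first-label ties", {
  m <- shared_fit
  m$weights <- lapply(m$weights, function(w) w * 0)
  m$biases <- lapply(m$biases, function(b) b * 0)
  P <- forward_probs(m, shared_feats[1:3, ])
  expect_equal(unname(P), matrix(1 / 7, 3, 7))
  expect_identical(unique(predict(m, shared_feats[1:3, ])),
                   m$label_order[1])
})

test_that("cross-entropy matches its closed forms", {
  labs <- movement_labels()
  perfect <- as.numeric(labs == "R")
  expect_equal(cross_entropy(perfect, "R", labs), 0)
  expect_equal(cross_entropy(rep(1 / 7, 7), "U", labs), log(7))
  # more mass on the true class means lower loss
  p1 <- c(0.4, rep(0.1, 6))
  p2 <- c(0.7, rep(0.05, 6))
  expect_gt(cross_entropy(p1, labs[1], labs), cross_entropy(p2, labs[1], labs))
  expect_error(cross_entropy(c(0.5, 0.4), labs[1], labs), "probability")
})

test_that("backprop gradients match central finite differences", {
  set.seed(13)
  for (act in c("sigmoid", "relu")) {
    sizes <- c(4, 3, 3, 2)
    params <- wristemg:::bpnn_init(sizes, seed = 17)
    # nonzero biases keep every relu pre-activation away from the kink,
    # where a finite difference would straddle the subgradient
    params$b <- lapply(params$b, function(b) b + 0.1 * seq_along(b))
    X <- matrix(rnorm(5 * 4), 5, 4)
    Y <- diag(2)[sample(1:2, 5, replace = TRUE), ]
    ana <- wristemg:::bpnn_loss_grad(params, X, Y, act)
    eps <- 1e-6
    for (l in 1:3) {
      idx <- cbind(sample(nrow(params$W[[l]]), 2, replace = TRUE),
                   sample(ncol(params$W[[l]]), 2, replace = TRUE))
      for (r in 1:2) {
        p_hi <- params; p_lo <- params
        p_hi$W[[l]][idx[r, 1], idx[r, 2]] <- p_hi$W[[l]][idx[r, 1], idx[r, 2]] + eps
        p_lo$W[[l]][idx[r, 1], idx[r, 2]] <- p_lo$W[[l]][idx[r, 1], idx[r, 2]] - eps
        num <- (wristemg:::bpnn_loss_grad(p_hi, X, Y, act)$loss -
                  wristemg:::bpnn_loss_grad(p_lo, X, Y, act)$loss) / (2 * eps)
        expect_lt(abs(ana$gW[[l]][idx[r, 1], idx[r, 2]] - num) /
                    max(abs(num), 1e-2), 1e-5)
      }
      b_hi <- params; b_lo <- params
      b_hi$b[[l]][1] <- b_hi$b[[l]][1] + eps
      b_lo$b[[l]][1] <- b_lo$b[[l]][1] - eps
      num <- (wristemg:::bpnn_loss_grad(b_hi, X, Y, act)$loss -
                wristemg:::bpnn_loss_grad(b_lo, X, Y, act)$loss) / (2 * eps)
      expect_lt(abs(ana$gb[[l]][1] - num) / max(abs(num), 1e-2), 1e-5)
    }
  }
})

test_that("initial per-sample loss sits near log(7) for balanced classes", {
  n_train <- length(shared_fit$loss_curve)
  stopifnot(n_train > 0)
  n_tr_samples <- round(0.8 * 20) * 7
  expect_lt(abs(shared_fit$loss_curve[1] / n_tr_samples - log(7)), 0.2)
})

test_that("training is deterministic under a fixed seed", {
  feats <- project_features(shared_feats, shared_sel)
  f1 <- train_bpnn(feats, iterations = 50, seed = 3)
  f2 <- train_bpnn(feats, iterations = 50, seed = 3)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$loss_curve, f2$loss_curve)
  f3 <- train_bpnn(feats, iterations = 50, seed = 4)
  expect_false(identical(f1$weights, f3$weights))
})

test_that("the loss trend is nonincreasing and the fit separates the classes", {
  lc <- shared_fit$loss_curve
  # smoothed trend: mean over 100-iteration blocks must decline
  blocks <- colMeans(matrix(lc[1:1500], nrow = 100))
  expect_true(all(diff(blocks) <= 0))
  expect_gte(shared_fit$test_accuracy, 0.95)
  expect_gte(shared_fit$train_accuracy, 0.99)
})

test_that("shuffled labels collapse held-out accuracy to chance", {
  feats <- project_features(shared_feats, shared_sel)
  feats$label <- wristemg:::with_seed(202, sample(feats$label))
  fit <- train_bpnn(feats, iterations = 300, seed = 5)
  expect_lt(abs(fit$test_accuracy - 1 / 7), 0.08)
})

test_that("the network does at least as well as a linear baseline", {
  skip_if_not_installed("nnet")
  feats <- project_features(shared_feats, shared_sel)
  base <- nnet::multinom(
    factor(label) ~ ., data = as.data.frame(feats[c("label", shared_sel)]),
    trace = FALSE)
  base_acc <- mean(predict(base) == feats$label)
  full_acc <- mean(predict(shared_fit, feats) == feats$label)
  expect_gte(full_acc, base_acc - 0.01)
})

test_that("dimension mismatches and bad configs are rejected", {
  expect_error(forward_probs(shared_fit, shared_feats[c("window", "label")]),
               "Missing feature")
  expect_error(train_bpnn(shared_feats, learning_rate = 0), "positive")
  expect_error(train_bpnn(shared_feats, train_fraction = 1), "between")
})

test_that("a serialized model predicts identically after reload", {
  path <- withr::local_tempfile(fileext = ".json")
  write_bpnn(shared_fit, path)
  back <- read_bpnn(path)
  expect_equal(back$weights, shared_fit$weights)
  expect_identical(predict(back, shared_feats),
                   predict(shared_fit, shared_feats))
})
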