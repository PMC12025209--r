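#' Hidden-layer sizing heuristic
#'
#' Number of neurons per hidden layer for an `m`-input, `n`-output network:
#' `M = round(sqrt(m + n)) + a` with the tuning constant `a` in \[0, 10\]
#' and rounding half-up. With the pipeline's 16 selected features, 7 output
#' classes and `a = 10` this gives `M = 15`.
#'
#' @param m Input-node count (>= 1).
#' @param n Output-node count (>= 1).
#' @param a Integer tuning constant in \[0, 10\].
#' @return Integer neuron count, at least 1.
#' @export
#' @examples
#' hidden_size(16, 7, 10)  # 15
hidden_size <- function(m, n, a = 10) {
  if (m < 1 || n < 1) abort("`m` and `n` must be >= 1.")
  if (a < 0 || a > 10) abort("`a` must lie in [0, 10].")
  max(1L, as.integer(round_half_up(sqrt(m + n)) + round(a)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

# Glorot-uniform initialization, seeded.
bpnn_init <- function(layer_sizes, seed) {
  with_seed(seed, {
    L <- length(layer_sizes) - 1
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      r <- sqrt(6 / (layer_sizes[l] + layer_sizes[l + 1]))
      W[[l]] <- matrix(runif(layer_sizes[l] * layer_sizes[l + 1], -r, r),
                       layer_sizes[l], layer_sizes[l + 1])
      b[[l]] <- rep(0, layer_sizes[l + 1])
    }
    list(W = W, b = b)
  })
}

act_fun <- function(activation) {
  switch(activation,
         sigmoid = list(f = sigmoid, df = function(a) a * (1 - a)),
         relu = list(f = function(z) pmax(z, 0),
                     df = function(a) as.numeric(a > 0)),
         abort("`activation` must be 'sigmoid' or 'relu'."))
}

# Forward pass; X is n x d (already standardized). Returns activations of
# every layer; probs is the softmax output.
bpnn_forward_pass <- function(params, X, activation) {
  g <- act_fun(activation)
  L <- length(params$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L - 1)) {
    A[[l + 1]] <- g$f(sweep(A[[l]] %*% params$W[[l]], 2, params$b[[l]], "+"))
  }
  Z <- sweep(A[[L]] %*% params$W[[L]], 2, params$b[[L]], "+")
  list(A = A, probs = softmax_rows(Z))
}

# Summed cross-entropy loss and its gradients (softmax output layer).
bpnn_loss_grad <- function(params, X, Y, activation) {
  g <- act_fun(activation)
  fw <- bpnn_forward_pass(params, X, activation)
  P <- fw$probs
  L <- length(params$W)
  loss <- -sum(log(pmax(P[Y > 0], .Machine$double.xmin)))
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- P - Y
  for (l in L:1) {
    gW[[l]] <- t(fw$A[[l]]) %*% delta
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(params$W[[l]])) * g$df(fw$A[[l]])
    }
  }
  list(loss = loss, gW = gW, gb = gb)
}

#' Train the backpropagation neural-network classifier
#'
#' Fits a two-hidden-layer perceptron mapping the selected time-domain
#' features to the seven wrist movements. The architecture is
#' `d -> M -> M -> K` with `M = hidden_size(d, K, a)` unless `hidden` is
#' given, sigmoid (default) hidden activations and a softmax output. The
#' data are split into stratified training and held-out sets, features are
#' standardized with training-set statistics, and weights are updated by
#' full-batch gradient descent on the summed cross-entropy loss
#' `L = -sum_i y_i log(yhat_i)` at a fixed learning rate.
#'
#' @param features Labeled feature tibble (typically 16 columns after
#'   [select_top_per_channel()] / [project_features()]).
#' @param hidden Neurons per hidden layer; `NULL` (default) uses
#'   [hidden_size()] with `a`.
#' @param a Sizing constant passed to [hidden_size()]. Default 10.
#' @param activation `"sigmoid"` (default) or `"relu"` hidden nonlinearity.
#' @param learning_rate Gradient-descent step size. Default 0.001.
#' @param iterations Full-batch iterations. Default 50000; a few thousand
#'   suffice on cleanly separable data.
#' @param train_fraction Fraction of each class used for training. Default
#'   0.8.
#' @param seed RNG seed for the split and the weight initialization.
#' @return An object of class `bpnn` with the fitted weights, the label
#'   order, standardization statistics, the loss curve and train/test
#'   accuracies. Methods: [predict.bpnn()], [tidy.bpnn()], [glance.bpnn()],
#'   [autoplot.bpnn()].
#' @export
#' @examples
#' feats <- generate_feature_dataset(windows_per_movement = 20,
#'                                   config = generator_config(seed = 5))
#' sel <- select_top_per_channel(relieff_weights(feats, k_neighbors = 5))
#' fit <- train_bpnn(project_features(feats, sel), iterations = 500, seed = 7)
#' glance(fit)
train_bpnn <- function(features, hidden = NULL, a = 10,
                       activation = c("sigmoid", "relu"),
                       learning_rate = 0.001, iterations = 50000,
                       train_fraction = 0.8, seed = 1) {
  activation <- match.arg(activation)
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  cols <- feature_cols(features)
  if (length(cols) == 0) abort("`features` has no recognizable feature columns.")
  if (!"label" %in% names(features) || anyNA(features$label)) {
    abort("`features` must have a complete `label` column.")
  }
  y <- as.character(features$label)
  labs <- unique(y)
  label_order <- c(intersect(movement_labels(), labs),
                   sort(setdiff(labs, movement_labels())))
  K <- length(label_order)
  if (any(table(y) < 2)) abort("Every class needs at least 2 instances.")
  X <- as.matrix(features[cols])

  # stratified split
  test_idx <- with_seed(derive_seed(seed, 977), {
    unlist(lapply(label_order, function(cl) {
      ids <- which(y == cl)
      n_test <- max(1L, round(length(ids) * (1 - train_fraction)))
      sample(ids, n_test)
    }))
  })
  train_idx <- setdiff(seq_len(nrow(X)), test_idx)

  center <- colMeans(X[train_idx, , drop = FALSE])
  scl <- apply(X[train_idx, , drop = FALSE], 2, sd)
  scl[scl == 0] <- 1
  std <- function(M) sweep(sweep(M, 2, center), 2, scl, "/")
  Xtr <- std(X[train_idx, , drop = FALSE])
  Ytr <- diag(K)[match(y[train_idx], label_order), , drop = FALSE]

  M <- if (is.null(hidden)) hidden_size(length(cols), K, a) else as.integer(hidden)
  layer_sizes <- c(length(cols), M, M, K)
  params <- bpnn_init(layer_sizes, derive_seed(seed, 1231))

  loss_curve <- numeric(iterations)
  for (it in seq_len(iterations)) {
    lg <- bpnn_loss_grad(params, Xtr, Ytr, activation)
    if (!is.finite(lg$loss)) {
      abort(sprintf("Non-finite loss at iteration %d; lower the learning rate.", it))
    }
    loss_curve[it] <- lg$loss
    for (l in seq_along(params$W)) {
      params$W[[l]] <- params$W[[l]] - learning_rate * lg$gW[[l]]
      params$b[[l]] <- params$b[[l]] - learning_rate * lg$gb[[l]]
    }
  }

  params$W <- lapply(params$W, unname)
  model <- structure(list(layer_sizes = layer_sizes, weights = params$W,
                          biases = params$b, activation = activation,
                          label_order = label_order, feature_names = cols,
                          center = center, scale = scl,
                          learning_rate = learning_rate,
                          iterations = iterations, seed = seed),
                     class = "bpnn")

  pr_tr <- predict(model, features[train_idx, ])
  pr_te <- predict(model, features[test_idx, ])
  model$train_accuracy <- mean(pr_tr == y[train_idx])
  model$test_accuracy <- mean(pr_te == y[test_idx])
  model$final_loss <- loss_curve[iterations]
  model$loss_curve <- loss_curve
  model$test_truth <- y[test_idx]
  model$test_pred <- pr_te
  model
}

#' @export
print.bpnn <- function(x, ...) {
  cat(sprintf("<bpnn> layers %s (%s), lr = %g, %d iterations\n",
              paste(x$layer_sizes, collapse = "-"), x$activation,
              x$learning_rate, x$iterations))
  cat(sprintf("  train accuracy %.3f | held-out accuracy %.3f | final loss %.4g\n",
              x$train_accuracy, x$test_accuracy, x$final_loss))
  invisible(x)
}

#' Class probabilities from a fitted network
#'
#' Runs the forward pass on raw (unstandardized) features; the model's
#' stored training-set standardization is applied internally, so features
#' must not be pre-standardized by the caller.
#'
#' @param model A fitted `bpnn`.
#' @param features Feature tibble (or matrix) holding the model's feature
#'   columns.
#' @return A numeric matrix, one row per instance, columns named by the
#'   model's `label_order`; rows lie on the probability simplex.
#' @export
forward_probs <- function(model, features) {
  if (!inherits(model, "bpnn")) abort("`model` must be a fitted bpnn.")
  if (is.data.frame(features)) {
    missing <- setdiff(model$feature_names, names(features))
    if (length(missing) > 0) {
      abort(paste0("Missing feature column(s): ", paste(missing, collapse = ", ")))
    }
    X <- as.matrix(features[model$feature_names])
  } else {
    X <- rbind(features)
    if (ncol(X) != model$layer_sizes[1]) abort("Feature dimension mismatch.")
  }
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  P <- bpnn_forward_pass(list(W = model$weights, b = model$biases), Xs,
                         model$activation)$probs
  colnames(P) <- model$label_order
  P
}

#' Predict movement labels
#'
#' @param object A fitted `bpnn`.
#' @param newdata Feature tibble with the model's feature columns (raw
#'   values; standardization is internal).
#' @param type `"class"` (default) for labels, `"prob"` for the probability
#'   matrix.
#' @param ... Unused.
#' @return Character vector of labels, or the probability matrix. Exact
#'   probability ties go to the label earlier in the model's `label_order`.
#' @export
predict.bpnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  P <- forward_probs(object, newdata)
  if (type == "prob") return(P)
  object$label_order[max.col(P, ties.method = "first")]
}

#' Cross-entropy of a predicted class distribution
#'
#' `-log` of the probability the prediction assigns to the true class
#' (one-hot reference). Zero probabilities are clamped to the smallest
#' positive double before the log.
#'
#' @param predicted Probability vector over classes (sums to 1).
#' @param true_class The true label.
#' @param label_order Character vector ordering the classes of `predicted`.
#' @return Nonnegative loss value.
#' @export
#' @examples
#' cross_entropy(rep(1 / 7, 7), "R", movement_labels())  # log(7)
cross_entropy <- function(predicted, true_class, label_order) {
  if (abs(sum(predicted) - 1) > 1e-6 || any(predicted < 0)) {
    abort("`predicted` must be a probability vector.")
  }
  i <- match(true_class, label_order)
  if (is.na(i)) abort("`true_class` not found in `label_order`.")
  -log(max(predicted[i], .Machine$double.xmin))
}

#' @describeIn train_bpnn Per-class held-out counts and accuracy.
#' @param x,object A fitted `bpnn`.
#' @param ... Unused.
#' @export
tidy.bpnn <- function(x, ...) {
  tibble(label = x$test_truth, pred = x$test_pred) %>%
    group_by(label = factor(.data$label, levels = x$label_order)) %>%
    summarise(n = n(), correct = sum(.data$label == .data$pred),
              accuracy = .data$correct / .data$n, .groups = "drop") %>%
    mutate(label = as.character(.data$label))
}

#' @describeIn train_bpnn One-row model summary.
#' @export
glance.bpnn <- function(x, ...) {
  tibble(hidden = x$layer_sizes[2], activation = x$activation,
         learning_rate = x$learning_rate, iterations = x$iterations,
         final_loss = x$final_loss, train_accuracy = x$train_accuracy,
         test_accuracy = x$test_accuracy)
}
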