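#' ReliefF feature weights
#'
#' Multiclass ReliefF: for each sampled instance, find its `k_neighbors`
#' nearest hits (same class) and, for every other class, its `k_neighbors`
#' nearest misses; a feature's weight is decreased by the mean feature
#' difference to hits and increased by the prior-weighted mean difference to
#' misses,
#' `W[f] <- W[f] - diff_hits/(m*k) + sum_C P(C)/(1 - P(class)) * diff_miss_C/(m*k)`,
#' over `m` sampled instances. Features are min-max normalized to \[0, 1\]
#' per column before both the Manhattan nearest-neighbor distances and the
#' `diff` terms, so weights are invariant to feature rescaling. Constant
#' features receive weight exactly 0.
#'
#' @param features A labeled feature tibble (a `label` column plus feature
#'   columns, e.g. from [extract_features()]).
#' @param k_neighbors Nearest hits/misses per class. Default 10.
#' @param n_iterations Number of sampled instances, or `NULL` (default) to
#'   iterate over every instance exhaustively (deterministic, no sampling
#'   noise).
#' @param seed RNG seed, used only when `n_iterations` subsamples.
#' @return An object of class `relieff_weights`: a list with a `weights`
#'   tibble (`feature`, `channel`, `stat`, `weight`) and the parameters.
#' @export
#' @examples
#' feats <- generate_feature_dataset(windows_per_movement = 15,
#'                                   config = generator_config(seed = 3))
#' w <- relieff_weights(feats)
#' head(tidy(w))
relieff_weights <- function(features, k_neighbors = 10, n_iterations = NULL,
                            seed = 1) {
  cols <- feature_cols(features)
  if (length(cols) == 0) abort("`features` has no recognizable feature columns.")
  if (!"label" %in% names(features) || anyNA(features$label)) {
    abort("`features` must have a complete `label` column.")
  }
  X <- as.matrix(features[cols])
  y <- as.character(features$label)
  n <- nrow(X)
  classes <- unique(y)
  if (length(classes) < 2) abort("At least 2 classes are required.")
  tab <- table(y)
  small <- names(tab)[tab <= k_neighbors]
  if (length(small) > 0) {
    abort(sprintf("Class '%s' has %d instances; more than k_neighbors = %d are required.",
                  small[1], tab[small[1]], k_neighbors))
  }

  # min-max normalize; constant columns contribute no diff at all
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  denom <- ifelse(span > 0, span, 1)
  Xn <- sweep(sweep(X, 2, rng[1, ]), 2, denom, "/")

  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  prior <- as.numeric(tab[classes]) / n
  names(prior) <- classes

  idx <- if (is.null(n_iterations) || n_iterations >= n) {
    seq_len(n)
  } else {
    with_seed(seed, sample.int(n, n_iterations))
  }
  m <- length(idx)
  k <- k_neighbors
  w <- numeric(length(cols))
  for (i in idx) {
    d <- D[i, ]
    d[i] <- Inf
    same <- which(y == y[i])
    hits <- same[order(d[same])][seq_len(k)]
    w <- w - colSums(abs(Xn[hits, , drop = FALSE] -
                           matrix(Xn[i, ], k, length(cols), byrow = TRUE))) /
      (m * k)
    for (cl in classes[classes != y[i]]) {
      oth <- which(y == cl)
      miss <- oth[order(d[oth])][seq_len(k)]
      scale <- prior[cl] / (1 - prior[y[i]])
      w <- w + scale *
        colSums(abs(Xn[miss, , drop = FALSE] -
                      matrix(Xn[i, ], k, length(cols), byrow = TRUE))) /
        (m * k)
    }
  }

  weights <- tibble(feature = cols,
                    channel = sub("_(MAV|RMS|VAR|ZC|WL)$", "", cols),
                    stat = sub("^ch[0-9]+_", "", cols),
                    weight = unname(w))
  structure(list(weights = weights, k_neighbors = k_neighbors,
                 n_iterations = m, seed = seed),
            class = "relieff_weights")
}

#' @export
print.relieff_weights <- function(x, ...) {
  cat(sprintf("<relieff_weights> %d features, k = %d, %d iterations\n",
              nrow(x$weights), x$k_neighbors, x$n_iterations))
  print(x$weights, ...)
  invisible(x)
}

#' @export
tidy.relieff_weights <- function(x, ...) {
  arrange(x$weights, desc(.data$weight))
}

#' Keep the highest-weight features of each channel
#'
#' Selects, per channel, the `per_channel` features with the largest ReliefF
#' weights. With 8 channels and the default `per_channel = 2` this yields
#' the 16-feature classifier input. Ties at the selection boundary are
#' resolved by the fixed feature order MAV < RMS < VAR < ZC < WL.
#'
#' @param weights A `relieff_weights` object (or its `weights` tibble).
#' @param per_channel Features to keep per channel. Default 2.
#' @return Character vector of selected feature names in channel-major
#'   order.
#' @export
select_top_per_channel <- function(weights, per_channel = 2) {
  w <- if (inherits(weights, "relieff_weights")) weights$weights else weights
  w <- w %>%
    mutate(stat_rank = match(.data$stat, feature_stats),
           ch_rank = as.integer(sub("ch", "", .data$channel))) %>%
    group_by(.data$channel) %>%
    arrange(desc(.data$weight), .data$stat_rank, .by_group = TRUE) %>%
    dplyr::slice_head(n = per_channel) %>%
    ungroup() %>%
    arrange(.data$ch_rank, .data$stat_rank)
  w$feature
}

#' Subset a feature tibble to selected features
#'
#' Keeps the metadata columns (`window`, `t_center`, `label`) and the
#' selected feature columns, in the order given; row order and labels are
#' preserved. Projection is idempotent.
#'
#' @param features A feature tibble.
#' @param selected Character vector of feature names to keep.
#' @return The projected tibble.
#' @export
project_features <- function(features, selected) {
  missing <- setdiff(selected, names(features))
  if (length(missing) > 0) {
    abort(paste0("Unknown feature name(s): ", paste(missing, collapse = ", ")))
  }
  meta <- intersect(c("window", "t_center", "label"), names(features))
  features[c(meta, selected)]
}
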