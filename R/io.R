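# Plain-text serialization: recordings and feature tables as CSV with a
# commented metadata preamble; fitted networks and force models as JSON.

#' Write / read a recording as CSV
#'
#' One sample per row, header `t,ch1..ch8`, metadata (sampling rate,
#' movement, load) in `#`-commented preamble lines.
#'
#' @param recording An `emg_recording`.
#' @param path File path.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an `emg_recording`.
#' @export
write_recording <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate: %s", attr(recording, "sampling_rate")),
               sprintf("# movement: %s", attr(recording, "movement")),
               sprintf("# load: %s", attr(recording, "load"))), con)
  utils::write.csv(as.data.frame(recording), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param path File path.
#' @export
read_recording <- function(path) {
  header <- readLines(path, n = 10)
  meta <- header[startsWith(header, "#")]
  get_meta <- function(key) {
    line <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(line) == 0) return(NA_character_)
    trimws(sub(paste0("^# ", key, ":"), "", line[1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  load <- suppressWarnings(as.numeric(get_meta("load")))
  mv <- get_meta("movement")
  new_emg_recording(as_tibble(df),
                    sampling_rate = as.numeric(get_meta("sampling_rate")),
                    movement = if (identical(mv, "NA")) NA_character_ else mv,
                    load = load)
}

#' Write / read a fitted network as JSON
#'
#' Serializes layer sizes, weights, biases, activation, label order and
#' standardization statistics; accuracy fields and the loss curve are
#' echoed when present.
#'
#' @param model A fitted `bpnn`.
#' @param path File path.
#' @return `write_bpnn()` returns `path` invisibly; `read_bpnn()` a `bpnn`.
#' @export
write_bpnn <- function(model, path) {
  payload <- list(
    layer_sizes = model$layer_sizes,
    weights = purrr::map(model$weights, ~ as.vector(t(.x))),
    biases = model$biases,
    activation = model$activation,
    label_order = model$label_order,
    feature_names = model$feature_names,
    center = as.list(model$center), scale = as.list(model$scale),
    learning_rate = model$learning_rate, iterations = model$iterations,
    seed = model$seed,
    train_accuracy = model$train_accuracy,
    test_accuracy = model$test_accuracy)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bpnn
#' @export
read_bpnn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(p$layer_sizes)
  W <- purrr::map(seq_len(length(sizes) - 1), function(l) {
    matrix(p$weights[[l]], sizes[l], sizes[l + 1], byrow = TRUE)
  })
  structure(list(layer_sizes = sizes, weights = W,
                 biases = purrr::map(p$biases, as.numeric),
                 activation = p$activation, label_order = p$label_order,
                 feature_names = p$feature_names,
                 center = unlist(p$center), scale = unlist(p$scale),
                 learning_rate = p$learning_rate, iterations = p$iterations,
                 seed = p$seed, train_accuracy = p$train_accuracy,
                 test_accuracy = p$test_accuracy),
            class = "bpnn")
}

#' Write a labeled feature table as CSV
#'
#' @param features A feature tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- as_tibble(utils::read.csv(path, check.names = FALSE))
  df
}

#' Write / read a static force model as JSON
#'
#' @param model A `static_force_model`.
#' @param path File path.
#' @return `write_static_model()` returns `path` invisibly.
#' @export
write_static_model <- function(model, path) {
  jsonlite::write_json(list(movement = model$movement, slope = model$slope,
                            intercept = model$intercept),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_static_model
#' @export
read_static_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  static_force_model(p$movement, p$slope, p$intercept)
}
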