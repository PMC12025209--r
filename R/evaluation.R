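#' Accuracy report from per-movement outcome counts
#'
#' Turns per-movement totals and error counts into per-movement and overall
#' accuracies. Accuracies are kept as exact fractions; the `percent` column
#' is a display value rounded half-up to one decimal and never feeds back
#' into any computation.
#'
#' @param counts Tibble with columns `movement`, `total`, `incorrect`.
#' @return An object of class `accuracy_report`: list with `by_movement`
#'   (tibble adding `correct`, `accuracy`, `percent`) and `overall` (one-row
#'   tibble).
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   movement = c("R", "U", "F-S", "F-L", "E-S", "E-L"),
#'   total = 300, incorrect = c(0, 1, 1, 15, 1, 5))
#' accuracy_from_counts(counts)$overall$percent  # 98.7
accuracy_from_counts <- function(counts) {
  need <- c("movement", "total", "incorrect")
  if (!all(need %in% names(counts))) {
    abort("`counts` needs columns movement, total, incorrect.")
  }
  if (any(counts$incorrect < 0) || any(counts$incorrect > counts$total)) {
    abort("Each `incorrect` must satisfy 0 <= incorrect <= total.")
  }
  by_movement <- as_tibble(counts) %>%
    mutate(correct = .data$total - .data$incorrect,
           accuracy = .data$correct / .data$total,
           percent = round_half_up(100 * .data$accuracy, 1))
  overall <- tibble(total = sum(counts$total),
                    incorrect = sum(counts$incorrect)) %>%
    mutate(correct = .data$total - .data$incorrect,
           accuracy = .data$correct / .data$total,
           percent = round_half_up(100 * .data$accuracy, 1))
  structure(list(by_movement = by_movement, overall = overall),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>\n")
  print(x$by_movement, ...)
  cat(sprintf("Overall: %d/%d correct (%.1f%%)\n", x$overall$correct,
              x$overall$total, x$overall$percent))
  invisible(x)
}

#' @export
tidy.accuracy_report <- function(x, ...) x$by_movement

#' @export
glance.accuracy_report <- function(x, ...) x$overall

#' Compare raw and voted classification accuracy
#'
#' @param raw_trace,voted_trace,truth Aligned label vectors of equal
#'   length.
#' @return One-row tibble with `raw_accuracy`, `voted_accuracy` and
#'   `improvement` (voted minus raw), all on \[0, 1\].
#' @export
#' @examples
#' truth <- rep("U", 100)
#' raw <- generate_label_stream(truth, 0.8, seed = 1)
#' compare_accuracy(raw, smooth_stream(raw), truth)
compare_accuracy <- function(raw_trace, voted_trace, truth) {
  n <- length(truth)
  if (length(raw_trace) != n || length(voted_trace) != n) {
    abort("All three traces must have equal length.")
  }
  raw_acc <- mean(raw_trace == truth)
  voted_acc <- mean(voted_trace == truth)
  tibble(raw_accuracy = raw_acc, voted_accuracy = voted_acc,
         improvement = voted_acc - raw_acc)
}
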