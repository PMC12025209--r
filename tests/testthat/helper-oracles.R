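# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementations.

bf_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

bf_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  sqrt(s / length(x))
}

bf_var <- function(x) {
  m <- 0
  for (v in x) m <- m + v
  m <- m / length(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  s / length(x)
}

bf_zc <- function(x, th) {
  cnt <- 0
  for (i in seq_len(length(x) - 1)) {
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) > th) cnt <- cnt + 1
  }
  cnt / length(x)
}

bf_wl <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s / length(x)
}

# Naive sliding majority-of-5 with the same tie contract (previous output if
# tied, else earliest occurrence in the window).
bf_smooth <- function(stream, width = 5) {
  out <- character(length(stream))
  prev <- NULL
  for (i in seq_along(stream)) {
    w <- stream[max(1, i - width + 1):i]
    counts <- table(w)
    tied <- names(counts)[counts == max(counts)]
    out[i] <- if (length(tied) == 1) {
      tied
    } else if (!is.null(prev) && prev %in% tied) {
      prev
    } else {
      tied[order(match(tied, w))][1]
    }
    prev <- out[i]
  }
  out
}

# Commands implied by maximal runs of length >= `required` (excluding rest).
bf_commands <- function(stream, required = 5) {
  r <- rle(stream)
  r$values[r$lengths >= required & r$values != "RELAX"]
}
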