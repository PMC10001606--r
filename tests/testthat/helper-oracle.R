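# Independent brute-force transcriptions of the degree formulas, written
# with explicit loops and no shared code with the package internals. Used
# as the oracle in equivalence tests on small sequences.

brute_mean_image <- function(x) {
  m <- 0
  for (v in x) m <- m + v
  m <- m / length(x)
  out <- numeric(length(x))
  for (k in seq_along(x)) out[k] <- x[k] / m
  out
}

brute_initial_image <- function(x) {
  out <- numeric(length(x))
  for (k in seq_along(x)) out[k] <- x[k] / x[1]
  out
}

brute_zero_start <- function(x) {
  out <- numeric(length(x))
  for (k in seq_along(x)) out[k] <- x[k] - x[1]
  out
}

# Deng's degree with global (two-level) min/max over all comparisons.
brute_deng <- function(x0, xs, eps = 0.5) {
  if (!is.list(xs)) xs <- list(xs)
  r <- brute_mean_image(x0)
  deltas <- list()
  dmin <- Inf
  dmax <- -Inf
  for (i in seq_along(xs)) {
    ci <- brute_mean_image(xs[[i]])
    d <- numeric(length(r))
    for (k in seq_along(r)) {
      d[k] <- abs(r[k] - ci[k])
      if (d[k] < dmin) dmin <- d[k]
      if (d[k] > dmax) dmax <- d[k]
    }
    deltas[[i]] <- d
  }
  out <- numeric(length(xs))
  for (i in seq_along(xs)) {
    total <- 0
    for (k in seq_along(r)) {
      g <- if (dmax == 0) 1 else
        (dmin + eps * dmax) / (deltas[[i]][k] + eps * dmax)
      total <- total + g
    }
    out[i] <- total / length(r)
  }
  out
}

brute_area <- function(x) {
  z <- brute_zero_start(x)
  s <- 0
  for (k in 2:(length(z) - 1)) s <- s + z[k]
  s + z[length(z)] / 2
}

brute_absolute <- function(x0, xi) {
  s0 <- brute_area(x0)
  si <- brute_area(xi)
  (1 + abs(s0) + abs(si)) / (1 + abs(s0) + abs(si) + abs(si - s0))
}

brute_relative <- function(x0, xi) {
  brute_absolute(brute_initial_image(x0), brute_initial_image(xi))
}

# Random small-integer sequence of length m (positive, so every image is
# well defined).
rand_small_seq <- function(m) sample(1:9, m, replace = TRUE)
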