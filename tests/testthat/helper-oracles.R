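# Brute-force oracles, kept independent of the package implementation.

# median by sorting, average-of-middle-two for even counts
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

oracle_robust_z <- function(x) {
  med <- oracle_median(x)
  mad_raw <- oracle_median(abs(x - med))
  (x - med) / (1.4826 * mad_raw)
}

# Spearman from the textbook d^2 formula (valid without ties)
oracle_spearman_noties <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# exhaustive confusion tally
oracle_confusion <- function(classes, called_pos) {
  out <- list()
  for (cl in sort(unique(classes))) {
    out[[cl]] <- c(positive = sum(classes == cl & called_pos),
                   negative = sum(classes == cl & !called_pos))
  }
  out
}

# closed-form OLS slope/intercept for the log-linear decay oracle
oracle_loglinear <- function(time, abundance) {
  y <- log(abundance)
  b <- sum((time - mean(time)) * (y - mean(y))) / sum((time - mean(time))^2)
  a <- mean(y) - b * mean(time)
  c(intercept = a, slope = b)
}
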