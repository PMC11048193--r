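# Independent brute-force oracles, written deliberately as plain loops so
# they share no code path with the package implementation.

oracle_pulse_stats <- function(x) {
  n <- length(x)
  s1 <- 0
  for (xi in x) s1 <- s1 + xi
  mu <- s1 / n
  s2 <- 0; s3 <- 0; s4 <- 0; ssq <- 0
  for (xi in x) {
    s2 <- s2 + (xi - mu)^2
    s3 <- s3 + (xi - mu)^3
    s4 <- s4 + (xi - mu)^4
    ssq <- ssq + xi^2
  }
  m2 <- s2 / n; m3 <- s3 / n; m4 <- s4 / n
  std <- sqrt(m2)
  rms <- sqrt(ssq / n)
  list(peak = max(x) - min(x),
       var = m2,
       std = std,
       rms = rms,
       sk = if (std > 0) m3 / (std * std * std) else NA_real_,
       ku = if (std > 0) m4 / (std * std * std * std) else NA_real_,
       wf = if (mu != 0) rms / mu else NA_real_,
       cl = if (mu != 0) (max(x) - min(x)) / mu^2 else NA_real_)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  cv <- 0; vx <- 0; vy <- 0
  for (i in seq_len(n)) {
    cv <- cv + (x[i] - mx) * (y[i] - my) / n
    vx <- vx + (x[i] - mx)^2 / n
    vy <- vy + (y[i] - my)^2 / n
  }
  cv / sqrt(vx * vy)
}

# labels realizing a given confusion-count matrix (rows actual, cols predicted)
labels_from_counts <- function(counts, classes) {
  y_true <- character(0); y_pred <- character(0)
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    k <- counts[i, j]
    y_true <- c(y_true, rep(classes[i], k))
    y_pred <- c(y_pred, rep(classes[j], k))
  }
  list(y_true = y_true, y_pred = y_pred)
}
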