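# Independent oracles for cross-checking the implementation paths.
# These deliberately use naive direct formulas, not the package routines.

# same-length zero-padded convolution by double loop (centre alignment
# matching instantaneous_frequency for an even-length kernel)
oracle_convolve <- function(x, k) {
  n <- length(x)
  m <- length(k)
  start <- floor((m + 1) / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(m)) {
      src <- i + start - 1 - (j - 1)   # full-conv index i+start-1 = src + j - 1
      if (src >= 1 && src <= n) acc <- acc + x[src] * k[j]
    }
    out[i] <- acc
  }
  out
}

# closed-form OLS slope
oracle_slope <- function(y) {
  x <- seq_along(y)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# textbook paired t statistic and two-sided p
oracle_paired_t <- function(a, b) {
  d <- a - b
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  list(t = t, p = 2 * stats::pt(-abs(t), length(d) - 1))
}

# periodogram argmax frequency (independent spectral estimator)
oracle_periodogram_peak <- function(x, fs, fmin = 1, fmax = 30) {
  pg <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          plot = FALSE, detrend = TRUE)
  sel <- pg$freq >= fmin & pg$freq <= fmax
  pg$freq[sel][which.max(pg$spec[sel])]
}

# Jaccard overlap of two interval sets, on a 1 ms grid of length n_ms
interval_jaccard <- function(a, b, n_ms) {
  t_ms <- seq_len(n_ms) - 1
  cover <- function(iv) {
    x <- rep(FALSE, n_ms)
    for (k in seq_len(nrow(iv)))
      x <- x | (t_ms >= iv$start_ms[k] & t_ms < iv$end_ms[k])
    x
  }
  ia <- cover(a); ib <- cover(b)
  sum(ia & ib) / sum(ia | ib)
}

# default-parameter simulated responses reused across tests
sim_train_response <- function(freq_hz, params, seed = 2, ...) {
  tr <- build_train(freq_hz)
  lowpass_angle(simulate_plant(tr, params, seed = seed, ...))
}
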