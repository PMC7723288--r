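# Independent oracles and tiny generators shared across tests. These stay
# deliberately naive (double loops, filter+max) so they check the package's
# vectorized paths from a different direction.

# Brute-force largest rise over ordered pairs, with the same tie-breaking
# contract (earliest start, then shortest span).
oracle_window_rise <- function(v) {
  best <- -Inf
  bi <- bj <- NA_integer_
  n <- length(v)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (v[j] - v[i] > best) {
        best <- v[j] - v[i]
        bi <- i
        bj <- j
      }
    }
  }
  list(rise = max(best, 0), start = bi, end = bj)
}

# Brute-force STT: enumerate every window whose last day lies in
# [end_lo, end_hi], take the max pairwise rise over each window's
# available values (outer(), a different route than the cummin scan).
oracle_stt <- function(sst, L, end_lo, end_hi, min_coverage = 0.8) {
  day <- as.integer(sst$date)
  need <- max(2L, as.integer(ceiling(min_coverage * L)))
  best <- -Inf
  for (e in as.integer(end_lo):as.integer(end_hi)) {
    inw <- day > e - L & day <= e
    if (sum(inw) < need) next
    v <- sst$value[inw]
    m <- outer(v, v, "-")        # m[j, i] = v[j] - v[i]
    best <- max(best, max(m[lower.tri(m)]))
  }
  if (!is.finite(best)) return(NA_real_)
  max(best, 0)
}

# Logistic map with optional observation noise, burn-in discarded.
gen_logistic <- function(n, r = 3.8, noise_sd = 0, burn = 100, x0 = NULL) {
  if (is.null(x0)) x0 <- runif(1, 0.2, 0.8)
  x <- numeric(n + burn)
  x[1] <- x0
  for (t in seq_len(n + burn - 1)) x[t + 1] <- r * x[t] * (1 - x[t])
  out <- x[(burn + 1):(burn + n)]
  if (noise_sd > 0) out <- pmax(out + rnorm(n, 0, noise_sd), 0)
  out
}

# Unidirectionally coupled logistic pair (driver x -> response y).
gen_coupled_logistic <- function(n, beta = 0.1, burn = 300) {
  x <- numeric(n + burn)
  y <- numeric(n + burn)
  x[1] <- runif(1, 0.2, 0.8)
  y[1] <- runif(1, 0.2, 0.8)
  for (t in seq_len(n + burn - 1)) {
    x[t + 1] <- x[t] * (3.8 - 3.8 * x[t])
    y[t + 1] <- y[t] * (3.5 - 3.5 * y[t] - beta * x[t])
  }
  idx <- (burn + 1):(burn + n)
  list(driver = x[idx], response = y[idx])
}

# Daily embedding of a numeric series with unit/2-day lags, plus a
# covariate; the standard fixture for the EDM benchmarks.
daily_embedding <- function(values, covariate = NULL, lags = c(1, 2)) {
  n <- length(values)
  d <- as.Date("2015-01-01") + 0:(n - 1)
  if (is.null(covariate)) covariate <- rep(0, n)
  build_embedding(sample_series(d, values),
                  daily_series(d, covariate), lags = lags, tolerance = 0)
}

# Leave-one-out global OLS prediction of x0 from the lag columns --
# the closed-form theta = 0 limit of the S-map, via stats::lm.
oracle_loo_ols <- function(embedding) {
  lagc <- paste0("lag_", attr(embedding, "lags"))
  df <- as.data.frame(embedding)[, c("x0", lagc)]
  vapply(seq_len(nrow(df)), function(i) {
    fit <- stats::lm(x0 ~ ., data = df[-i, ])
    unname(stats::predict(fit, newdata = df[i, ]))
  }, numeric(1))
}

# Noise-free, perfectly coupled study: flat-background SST with one
# triangular event per year, eggs exactly linear in the event magnitude.
noise_free_params <- function(seed = 1, n_years = 7, ...) {
  synthetic_params(n_years = n_years, sst_amplitude = 0, ar_sd = 0,
                   peak_noise_sd = 0, sampling_gap_range = c(1, 1),
                   seed = seed, ...)
}
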