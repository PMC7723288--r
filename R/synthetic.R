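#' Parameters for the synthetic pier-study generator
#'
#' Defines a multi-year paired dataset with the structure the trigger
#' analysis assumes: a seasonal sea-surface temperature cycle with AR(1)
#' daily fluctuations and one discrete spring warming event per year
#' (a triangular excursion: linear rise of `event_duration` days followed
#' by a linear fall of the same length, so the largest windowed rise
#' equals the event magnitude for any window longer than the rise), and an
#' egg series with a low baseline plus one Gaussian-shaped summer peak per
#' year whose height is linearly coupled to that year's true event
#' magnitude (or decoupled under `null_model`). Tows sample the latent
#' daily egg curve at irregular gaps.
#'
#' Magnitudes: a length-2 `event_magnitudes` (when `n_years != 2`) is a
#' uniform sampling range in degrees C; a vector of length `n_years` gives
#' fixed per-year magnitudes.
#'
#' All randomness is governed by `seed`: the per-year truth (event days,
#' magnitudes, peak days, height noise) uses `seed`, the SST AR(1) noise
#' uses `seed + 1`, and the tow-date sampling uses `seed + 2`, so
#' [generate_sst()] and [generate_eggs()] are individually deterministic
#' and mutually consistent. Identical parameters and seed give
#' bit-identical output.
#'
#' @param n_years number of study years.
#' @param start_year first calendar year.
#' @param sst_mean annual mean SST, degrees C.
#' @param sst_amplitude seasonal sinusoid amplitude, degrees C (peak mid
#'   July).
#' @param ar_coeff AR(1) coefficient of daily residuals, in `[0, 1)`.
#' @param ar_sd AR(1) innovation standard deviation, degrees C.
#' @param event_day_window day-of-year interval `[lo, hi]` in which the
#'   spring event's rise begins.
#' @param event_magnitudes event magnitudes, degrees C (range or per-year
#'   vector, see Details).
#' @param event_duration rise length of the event, days.
#' @param egg_baseline baseline eggs per tow.
#' @param coupling_slope eggs per tow per degree C of event magnitude.
#' @param coupling_intercept eggs per tow.
#' @param peak_noise_sd standard deviation of peak-height noise, eggs/tow.
#' @param peak_day_window day-of-year interval for the summer peak center.
#' @param peak_width Gaussian standard deviation of the peak, days.
#' @param sampling_gap_range `[min, max]` days between consecutive tows.
#' @param null_model if `TRUE`, peak heights are driven by freshly drawn
#'   magnitudes independent of the injected events (same marginal
#'   distribution), severing the coupling.
#' @param observation `"round"` (deterministic rounding of the latent
#'   curve) or `"poisson"` (Poisson counts with the latent mean).
#' @param seed integer seed.
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_years = 7L, start_year = 2013L,
                             sst_mean = 17, sst_amplitude = 4,
                             ar_coeff = 0.7, ar_sd = 0.3,
                             event_day_window = c(150L, 164L),
                             event_magnitudes = c(1, 5),
                             event_duration = 5L,
                             egg_baseline = 20,
                             coupling_slope = 150,
                             coupling_intercept = 100,
                             peak_noise_sd = 30,
                             peak_day_window = c(171L, 235L),
                             peak_width = 12,
                             sampling_gap_range = c(2L, 5L),
                             null_model = FALSE,
                             observation = c("round", "poisson"),
                             seed = 1L) {
  p <- list(n_years = as.integer(n_years), start_year = as.integer(start_year),
            sst_mean = sst_mean, sst_amplitude = sst_amplitude,
            ar_coeff = ar_coeff, ar_sd = ar_sd,
            event_day_window = as.integer(event_day_window),
            event_magnitudes = as.numeric(event_magnitudes),
            event_duration = as.integer(event_duration),
            egg_baseline = egg_baseline,
            coupling_slope = coupling_slope,
            coupling_intercept = coupling_intercept,
            peak_noise_sd = peak_noise_sd,
            peak_day_window = as.integer(peak_day_window),
            peak_width = peak_width,
            sampling_gap_range = as.integer(sampling_gap_range),
            null_model = isTRUE(null_model),
            observation = match.arg(observation),
            seed = as.integer(seed))
  if (p$n_years < 1L) stop("n_years must be >= 1")
  if (p$ar_coeff < 0 || p$ar_coeff >= 1) stop("ar_coeff must be in [0, 1)")
  if (p$ar_sd < 0 || p$sst_amplitude < 0) stop("sds/amplitudes must be >= 0")
  if (p$event_duration < 1L) stop("event_duration must be >= 1 day")
  if (any(p$event_magnitudes < 0)) stop("event magnitudes must be >= 0")
  if (p$peak_noise_sd < 0 || p$peak_width <= 0 || p$egg_baseline < 0) {
    stop("egg parameters must be nonnegative (peak_width > 0)")
  }
  if (length(p$event_day_window) != 2L || length(p$peak_day_window) != 2L ||
      p$event_day_window[1L] > p$event_day_window[2L] ||
      p$peak_day_window[1L] > p$peak_day_window[2L]) {
    stop("day-of-year windows must be [lo, hi] with lo <= hi")
  }
  if (p$event_day_window[2L] > p$peak_day_window[1L]) {
    stop("event_day_window must precede peak_day_window")
  }
  if (length(p$sampling_gap_range) != 2L ||
      p$sampling_gap_range[1L] < 1L ||
      p$sampling_gap_range[1L] > p$sampling_gap_range[2L]) {
    stop("sampling_gap_range must be [min, max] with 1 <= min <= max")
  }
  if (!(length(p$event_magnitudes) %in% c(2L, p$n_years))) {
    stop("event_magnitudes must be a [lo, hi] range or one value per year")
  }
  class(p) <- "synthetic_params"
  p
}

# Per-year ground truth. Always consumes the same RNG draws in the same
# order so that the truth is identical whether reached via generate_sst,
# generate_eggs or generate_study.
draw_truth <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  p <- params
  set.seed(p$seed)
  years <- p$start_year + seq_len(p$n_years) - 1L
  ew <- p$event_day_window
  event_doy <- ew[1L] + sample.int(ew[2L] - ew[1L] + 1L, p$n_years,
                                   replace = TRUE) - 1L
  per_year <- length(p$event_magnitudes) == p$n_years
  magnitude <- if (per_year) p$event_magnitudes else
    runif(p$n_years, p$event_magnitudes[1L], p$event_magnitudes[2L])
  pw <- p$peak_day_window
  peak_doy <- pw[1L] + sample.int(pw[2L] - pw[1L] + 1L, p$n_years,
                                  replace = TRUE) - 1L
  hnoise <- rnorm(p$n_years, 0, p$peak_noise_sd)
  null_mag <- if (per_year) magnitude[sample.int(p$n_years)] else
    runif(p$n_years, p$event_magnitudes[1L], p$event_magnitudes[2L])
  m_eff <- if (p$null_model) null_mag else magnitude
  height <- pmax(0, p$coupling_intercept + p$coupling_slope * m_eff + hnoise)
  jan1 <- as.Date(sprintf("%04d-01-01", years))
  data.frame(year = years,
             event_doy = event_doy,
             event_date = jan1 + event_doy - 1L,
             magnitude = magnitude,
             peak_doy = peak_doy,
             peak_date = jan1 + peak_doy - 1L,
             peak_height = p$egg_baseline + height)
}

#' Generate a synthetic daily SST series
#'
#' Seasonal sinusoid (period ~1 year, maximum in mid July) plus AR(1)
#' daily noise plus one triangular warming event per year (see
#' [synthetic_params()]).
#'
#' @param params a [synthetic_params()] object.
#' @return A [daily_series()] covering every day of the study years.
#' @export
generate_sst <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  p <- params
  truth <- draw_truth(p)
  d0 <- as.Date(sprintf("%04d-01-01", p$start_year))
  d1 <- as.Date(sprintf("%04d-12-31", p$start_year + p$n_years - 1L))
  dates <- seq(d0, d1, by = "day")
  doy <- as.POSIXlt(dates)$yday + 1L
  base <- p$sst_mean + p$sst_amplitude * cos(2 * pi * (doy - 196) / 365.25)
  set.seed(p$seed + 1L)
  innov <- rnorm(length(dates), 0, p$ar_sd)
  noise <- as.numeric(stats::filter(innov, p$ar_coeff, method = "recursive"))
  value <- base + noise
  dur <- p$event_duration
  day_index <- as.integer(dates) - as.integer(d0) + 1L
  for (y in seq_len(p$n_years)) {
    s <- as.integer(truth$event_date[y]) - as.integer(d0) + 1L
    k <- 0:(2L * dur)
    bump <- truth$magnitude[y] * ifelse(k <= dur, k / dur, (2 * dur - k) / dur)
    pos <- s + k
    ok <- pos >= 1L & pos <= length(dates)
    value[pos[ok]] <- value[pos[ok]] + bump[ok]
  }
  daily_series(dates, value, label = "synthetic sst")
}

#' Generate a synthetic egg-collection series
#'
#' The latent daily curve is `egg_baseline` plus one Gaussian summer peak
#' per year; the peak height is linear in that year's true event magnitude
#' (or in an independent draw under `null_model`). Tows sample the latent
#' curve at seeded gaps drawn uniformly from `sampling_gap_range`, and
#' counts are rounded to nonnegative integers (or Poisson-sampled).
#'
#' @param sst the matching [generate_sst()] output (defines the calendar).
#' @param params the same [synthetic_params()] used for `sst`.
#' @return A [sample_series()].
#' @export
generate_eggs <- function(sst, params) {
  stopifnot(inherits(sst, "daily_series"), inherits(params, "synthetic_params"))
  p <- params
  truth <- draw_truth(p)
  d0 <- as.Date(sprintf("%04d-01-01", p$start_year))
  d1 <- as.Date(sprintf("%04d-12-31", p$start_year + p$n_years - 1L))
  if (min(sst$date) > d0 || max(sst$date) < d1) {
    stop("sst does not span the study years of `params`")
  }
  dates <- seq(d0, d1, by = "day")
  t <- as.numeric(dates)
  latent <- rep(p$egg_baseline, length(dates))
  for (y in seq_len(p$n_years)) {
    amp <- truth$peak_height[y] - p$egg_baseline
    latent <- latent +
      amp * exp(-0.5 * ((t - as.numeric(truth$peak_date[y])) / p$peak_width)^2)
  }
  set.seed(p$seed + 2L)
  g <- p$sampling_gap_range
  n_max <- length(dates) %/% g[1L] + 2L
  gaps <- g[1L] + sample.int(g[2L] - g[1L] + 1L, n_max, replace = TRUE) - 1L
  pos <- cumsum(gaps)
  pos <- pos[pos <= length(dates)]
  lat <- latent[pos]
  obs <- if (p$observation == "poisson") rpois(length(lat), lat) else
    round(lat)
  sample_series(dates[pos], pmax(0, obs))
}

#' Generate a full synthetic study
#'
#' Convenience wrapper returning the SST series, the egg series, and the
#' per-year ground truth (event dates and magnitudes, latent peak dates
#' and heights) for recovery tests.
#'
#' @param params a [synthetic_params()] object.
#' @return A list with elements `sst` ([daily_series()]), `eggs`
#'   ([sample_series()]) and `truth` (data frame, one row per year).
#' @export
generate_study <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  sst <- generate_sst(params)
  eggs <- generate_eggs(sst, params)
  list(sst = sst, eggs = eggs, truth = draw_truth(params))
}
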