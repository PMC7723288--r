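# Structural-sensitivity audits: scans over the non-quantitative choices
# (window width, season boundaries, trigger timing, smoothing, delay) that
# an event-trigger analysis quietly fixes. Each scan returns a tidy data
# frame (grid columns + rho + n + valid); grid points that cannot support a
# correlation (n < 3 or zero variance) are marked invalid, never dropped.

scan_result <- function(df) {
  stopifnot(all(c("rho", "n", "valid") %in% names(df)))
  class(df) <- c("scan_result", "data.frame")
  df
}

# Per-year STT vector with the spring-end boundary shifted by `offset` days.
stt_vector <- function(sst, years, L, season, spring_end_offset = 0L,
                       min_coverage = 0.8, method = "pairwise") {
  vapply(years, function(y) {
    lo <- resolve_md(season$spring_start, y)
    hi <- resolve_md(season$spring_end, y) + spring_end_offset
    if (hi < lo) return(NA_real_)
    r <- tryCatch(
      compute_stt_range(sst, y, L, lo, hi, min_coverage, method),
      error = function(e) NULL)
    if (is.null(r)) NA_real_ else r$stt
  }, numeric(1L))
}

# Per-year peak summer eggs with the summer-start boundary shifted.
peak_vector <- function(eggs, years, season, summer_start_offset = 0L) {
  vapply(years, function(y) {
    lo <- resolve_md(season$summer_start, y) + summer_start_offset
    hi <- resolve_md(season$summer_end, y)
    if (hi < lo) return(NA_real_)
    sel <- eggs$date >= lo & eggs$date <= hi
    if (!any(sel)) NA_real_ else max(eggs$value[sel])
  }, numeric(1L))
}

safe_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  n <- sum(keep)
  if (n < 3L || sd(x[keep]) == 0 || sd(y[keep]) == 0) {
    list(rho = NA_real_, n = n, valid = FALSE)
  } else {
    list(rho = cor(x[keep], y[keep]), n = n, valid = TRUE)
  }
}

#' Window-width scan of the trigger-to-peak correlation
#'
#' For each window length `L` in `L_grid`, computes the per-year STT and
#' the per-year peak summer eggs and the Pearson correlation between them
#' across years. Exposes how the headline correlation depends on the
#' sliding-window width.
#'
#' @param sst a [daily_series()].
#' @param eggs a [sample_series()].
#' @param L_grid integer vector of window lengths (days, each `>= 2`).
#' @param season a [season_spec()].
#' @param min_coverage minimum within-window data fraction, see
#'   [compute_stt()].
#' @return A `scan_result` data frame with columns `L`, `rho`, `n`,
#'   `valid`.
#' @export
window_width_scan <- function(sst, eggs, L_grid = seq(14L, 42L, 7L),
                              season = season_spec(), min_coverage = 0.8) {
  L_grid <- as.integer(L_grid)
  if (any(L_grid < 2L)) stop("all window lengths must be >= 2 days")
  years <- sort(unique(series_years(eggs)))
  peaks <- peak_vector(eggs, years, season)
  rows <- lapply(L_grid, function(L) {
    stts <- stt_vector(sst, years, L, season, min_coverage = min_coverage)
    cc <- safe_cor(stts, peaks)
    data.frame(L = L, rho = cc$rho, n = cc$n, valid = cc$valid)
  })
  scan_result(do.call(rbind, rows))
}

#' Season-boundary sensitivity surface
#'
#' Shifts the spring end date (which bounds the trigger window traversal)
#' and the summer start date (which bounds the egg-peak interval) by
#' integer day offsets and recomputes the trigger-to-peak correlation in
#' every cell. The `(0, 0)` cell equals the unshifted analysis exactly.
#'
#' @inheritParams window_width_scan
#' @param spring_end_offsets,summer_start_offsets integer day shifts.
#' @param L window length in days.
#' @return A `scan_result` data frame with columns `spring_end_offset`,
#'   `summer_start_offset`, `rho`, `n`, `valid`.
#' @export
boundary_scan <- function(sst, eggs, spring_end_offsets = -21:21,
                          summer_start_offsets = -21:21, L = 28L,
                          season = season_spec(), min_coverage = 0.8) {
  years <- sort(unique(series_years(eggs)))
  stt_tab <- lapply(as.integer(spring_end_offsets), function(o) {
    stt_vector(sst, years, as.integer(L), season, o, min_coverage)
  })
  peak_tab <- lapply(as.integer(summer_start_offsets), function(o) {
    peak_vector(eggs, years, season, o)
  })
  grid <- expand.grid(spring_end_offset = as.integer(spring_end_offsets),
                      summer_start_offset = as.integer(summer_start_offsets))
  res <- mapply(function(i, j) {
    cc <- safe_cor(stt_tab[[i]], peak_tab[[j]])
    c(cc$rho, cc$n, cc$valid)
  },
  match(grid$spring_end_offset, as.integer(spring_end_offsets)),
  match(grid$summer_start_offset, as.integer(summer_start_offsets)))
  grid$rho <- res[1L, ]
  grid$n <- as.integer(res[2L, ])
  grid$valid <- as.logical(res[3L, ])
  scan_result(grid)
}

#' Any-time trigger versus annual peak
#'
#' Relaxes both season definitions: the annual egg peak is the maximum
#' collection anywhere in the calendar year, and the trigger window's last
#' day may fall anywhere from Jan 28 to the day immediately preceding that
#' year's peak. Years whose peak falls before Jan 29 are excluded with a
#' warning.
#'
#' @inheritParams window_width_scan
#' @param L window length in days.
#' @return List with `rho`, `n`, and `records` (per-year trigger, peak and
#'   peak date).
#' @export
anytime_trigger_scan <- function(sst, eggs, L = 28L, min_coverage = 0.8) {
  years <- sort(unique(series_years(eggs)))
  rows <- lapply(years, function(y) {
    pk <- tryCatch(
      peak_eggs(eggs, y, interval = list(start = c(1L, 1L), end = c(12L, 31L))),
      error = function(e) NULL)
    if (is.null(pk)) return(NULL)
    jan28 <- as.Date(sprintf("%04d-01-28", y))
    if (pk$peak_date <= jan28) {
      warning(sprintf("year %d: annual peak on %s precedes Jan 29; excluded",
                      y, format(pk$peak_date)), call. = FALSE)
      return(NULL)
    }
    tr <- tryCatch(
      compute_stt_range(sst, y, as.integer(L), jan28, pk$peak_date - 1L,
                        min_coverage),
      error = function(e) NULL)
    if (is.null(tr)) return(NULL)
    data.frame(year = y, trigger = tr$stt, peak = pk$peak,
               peak_date = pk$peak_date)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) < 3L) {
    stop("fewer than 3 usable years for the any-time trigger correlation")
  }
  cc <- safe_cor(rows$trigger, rows$peak)
  list(rho = cc$rho, n = cc$n, records = rows)
}

#' Smoothing-degradation scan
#'
#' Recomputes the trigger-to-peak correlation after smoothing the SST
#' series with centered moving averages of increasing width (daily to
#' monthly). Width 1 reproduces the unsmoothed analysis exactly.
#'
#' @inheritParams window_width_scan
#' @param widths odd integer smoothing widths in days.
#' @param L window length in days.
#' @return A `scan_result` data frame with columns `width`, `rho`, `n`,
#'   `valid`.
#' @export
smoothing_scan <- function(sst, eggs, widths = seq(1L, 31L, 2L), L = 28L,
                           season = season_spec(), min_coverage = 0.8) {
  widths <- as.integer(widths)
  if (any(widths < 1L | widths %% 2L == 0L)) {
    stop("smoothing widths must be odd and >= 1")
  }
  years <- sort(unique(series_years(eggs)))
  peaks <- peak_vector(eggs, years, season)
  rows <- lapply(widths, function(w) {
    sm <- moving_average(sst, w)
    stts <- stt_vector(sm, years, as.integer(L), season,
                       min_coverage = min_coverage)
    cc <- safe_cor(stts, peaks)
    data.frame(width = w, rho = cc$rho, n = cc$n, valid = cc$valid)
  })
  scan_result(do.call(rbind, rows))
}

#' Lagged daily cross-correlation between winter SST and egg abundance
#'
#' For each delay `d`, pairs every winter day `t` carrying an SST value
#' with the egg collection nearest to `t + d` (within
#' `match_tolerance` days; unpaired days are dropped) and reports the
#' Pearson correlation over the pairs.
#'
#' @inheritParams window_width_scan
#' @param delays nonnegative integer delays in days.
#' @param match_tolerance maximum date distance for pairing, days.
#' @return A `scan_result` data frame with columns `delay`, `rho`, `n`,
#'   `valid`.
#' @export
lagged_crosscorr <- function(sst, eggs, delays = 0:180,
                             season = season_spec(), match_tolerance = 2L) {
  delays <- as.integer(delays)
  if (any(delays < 0L)) stop("delays must be nonnegative")
  tol <- as.integer(match_tolerance)
  if (tol < 0L) stop("match_tolerance must be >= 0")
  years <- sort(unique(series_years(sst)))
  wsel <- rep(FALSE, nrow(sst))
  for (y in years) {
    iv <- season_interval(season, "winter", y)
    wsel <- wsel | (sst$date >= iv[1L] & sst$date <= iv[2L])
  }
  wd <- as.integer(sst$date[wsel])
  wv <- sst$value[wsel]
  ed <- as.integer(eggs$date)
  ev <- eggs$value
  rows <- lapply(delays, function(dl) {
    target <- wd + dl
    i <- findInterval(target, ed)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(ed))
    dist_lo <- abs(target - ed[lo])
    dist_hi <- abs(ed[hi] - target)
    use_lo <- i >= 1L & (dist_lo <= dist_hi | i + 1L > length(ed))
    nearest <- ifelse(use_lo, lo, hi)
    dist <- abs(ed[nearest] - target)
    keep <- i >= 0L & dist <= tol
    cc <- safe_cor(wv[keep], ev[nearest[keep]])
    data.frame(delay = dl, rho = cc$rho, n = cc$n, valid = cc$valid)
  })
  scan_result(do.call(rbind, rows))
}

#' Seasonal aggregate correlation
#'
#' The coarse-scale benchmark relationship: per year, the mean winter SST
#' (December of the preceding year through February) and the mean egg
#' abundance over March-August, with the Pearson correlation across
#' years. Years missing either seasonal average are excluded with a
#' warning.
#'
#' @inheritParams window_width_scan
#' @param spring_summer list with `(month, day)` elements `start` and
#'   `end` bounding the egg averaging interval (default Mar 1 - Aug 31).
#' @return List with `rho`, `n`, and `table` of per-year averages.
#' @export
seasonal_aggregate_corr <- function(sst, eggs, season = season_spec(),
                                    spring_summer = list(start = c(3L, 1L),
                                                         end = c(8L, 31L))) {
  years <- sort(unique(series_years(eggs)))
  rows <- lapply(years, function(y) {
    wiv <- season_interval(season, "winter", y)
    ws <- sst$value[sst$date >= wiv[1L] & sst$date <= wiv[2L]]
    lo <- resolve_md(as.integer(spring_summer$start), y)
    hi <- resolve_md(as.integer(spring_summer$end), y)
    es <- eggs$value[eggs$date >= lo & eggs$date <= hi]
    if (!length(ws) || !length(es)) {
      warning(sprintf("year %d: missing winter SST or Mar-Aug eggs; excluded",
                      y), call. = FALSE)
      return(NULL)
    }
    data.frame(year = y, winter_sst = mean(ws), egg_mean = mean(es))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) < 3L) {
    stop("fewer than 3 years with both seasonal averages")
  }
  if (sd(rows$winter_sst) == 0 || sd(rows$egg_mean) == 0) {
    stop("zero variance in a seasonal average: rho undefined")
  }
  list(rho = cor(rows$winter_sst, rows$egg_mean), n = nrow(rows),
       table = rows)
}

#' Correlation matrix of derived annual variables
#'
#' Pairwise Pearson correlations over years between the four derived
#' annual variables: STT, peak summer eggs, mean summer eggs, and mean
#' winter SST. Zero-variance variables have their row/column set to `NA`
#' (diagonal kept at 1) and are named in the `"invalid"` attribute.
#'
#' @inheritParams window_width_scan
#' @param L window length in days for the STT.
#' @return A symmetric 4x4 matrix with unit diagonal.
#' @export
annual_variable_matrix <- function(sst, eggs, season = season_spec(),
                                   L = 28L) {
  years <- sort(unique(series_years(eggs)))
  stt <- stt_vector(sst, years, as.integer(L), season)
  peak <- peak_vector(eggs, years, season)
  mean_summer <- vapply(years, function(y) {
    iv <- season_interval(season, "summer", y)
    v <- eggs$value[eggs$date >= iv[1L] & eggs$date <= iv[2L]]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1L))
  winter <- vapply(years, function(y) {
    iv <- season_interval(season, "winter", y)
    v <- sst$value[sst$date >= iv[1L] & sst$date <= iv[2L]]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1L))
  tab <- cbind(stt = stt, peak_summer_eggs = peak,
               mean_summer_eggs = mean_summer, mean_winter_sst = winter)
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  if (nrow(tab) < 3L) stop("fewer than 3 complete years")
  m <- diag(1, 4L)
  dimnames(m) <- list(colnames(tab), colnames(tab))
  sds <- apply(tab, 2L, sd)
  bad <- names(sds)[sds == 0]
  for (i in 1:3) for (j in (i + 1):4) {
    v <- if (sds[i] == 0 || sds[j] == 0) NA_real_ else cor(tab[, i], tab[, j])
    m[i, j] <- v
    m[j, i] <- v
  }
  attr(m, "n") <- nrow(tab)
  attr(m, "invalid") <- bad
  m
}
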