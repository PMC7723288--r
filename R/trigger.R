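#' Largest temperature rise within an ordered set of values
#'
#' The rise of a window is the maximum of `values[j] - values[i]` over
#' ordered pairs `i < j` (`method = "pairwise"`, the default), or the
#' last-minus-first difference (`method = "endpoints"`). When every pair
#' declines the rise is reported as 0 and the endpoints are those of the
#' least decline. Ties are broken by the earliest start, then the shortest
#' span.
#'
#' @param values numeric vector of at least 2 ordered daily temperatures.
#' @param method `"pairwise"` or `"endpoints"`.
#' @return A list with `rise` (degrees C, `>= 0`), `start` and `end`
#'   (1-based indices of the achieving pair).
#' @examples
#' window_rise(c(3, 1, 4, 1, 5)) # rise 4 from index 2 to 5
#' @export
window_rise <- function(values, method = c("pairwise", "endpoints")) {
  method <- match.arg(method)
  n <- length(values)
  if (n < 2L) stop("window_rise needs at least 2 values")
  if (anyNA(values)) stop("window_rise values must not contain NA")
  if (method == "endpoints") {
    return(list(rise = max(values[n] - values[1L], 0),
                start = 1L, end = n))
  }
  pm <- cummin(values)               # prefix minima
  diffs <- values[-1L] - pm[-n]      # best rise ending at each j
  best <- max(diffs)
  js <- which(diffs == best) + 1L
  is <- vapply(js, function(j) match(pm[j - 1L], values[seq_len(j - 1L)]),
               integer(1L))          # earliest index achieving the prefix min
  pick <- order(is, js)[1L]
  list(rise = max(best, 0), start = is[pick], end = js[pick])
}

#' Spring temperature trigger (STT) for one year
#'
#' The STT is the largest temperature rise found in any sliding window of
#' length `L` days whose last day lies inside the spring interval (both
#' traversal endpoints inclusive). Within a window the rise is
#' [window_rise()] over the window's available daily values. Window
#' positions with less than `min_coverage` of their `L` days present are
#' skipped; ties between window positions are broken by the earliest
#' window end date.
#'
#' @param sst a [daily_series()] of daily SST.
#' @param year calendar year.
#' @param L window length in days (`>= 2`).
#' @param season a [season_spec()].
#' @param min_coverage minimum fraction of window days with data.
#' @param method rise definition, see [window_rise()].
#' @return A list of class `trigger_result`: `year`, `stt` (degrees C),
#'   `window_length`, `window_end_date`, `rise_start_date`,
#'   `rise_end_date`.
#' @export
compute_stt <- function(sst, year, L = 28L, season = season_spec(),
                        min_coverage = 0.8,
                        method = c("pairwise", "endpoints")) {
  stopifnot(inherits(sst, "daily_series"))
  method <- match.arg(method)
  L <- as.integer(L)
  if (L < 2L) stop("window length L must be >= 2 days")
  sp <- season_interval(season, "spring", as.integer(year))
  compute_stt_range(sst, as.integer(year), L, sp[1L], sp[2L],
                    min_coverage, method)
}

# Shared engine: STT with the window's last day traversing [end_lo, end_hi].
compute_stt_range <- function(sst, year, L, end_lo, end_hi,
                              min_coverage = 0.8, method = "pairwise") {
  day <- as.integer(sst$date)
  lo <- as.integer(end_lo) - L + 1L
  hi <- as.integer(end_hi)
  sel <- day >= lo & day <= hi
  d <- day[sel]
  v <- sst$value[sel]
  need <- max(2L, as.integer(ceiling(min_coverage * L)))
  best <- NULL
  best_rise <- -Inf
  for (e in as.integer(end_lo):as.integer(end_hi)) {
    inw <- d > e - L & d <= e
    if (sum(inw) < need) next
    wr <- window_rise(v[inw], method = method)
    if (wr$rise > best_rise) {
      wd <- d[inw]
      best_rise <- wr$rise
      best <- list(end = e, start_day = wd[wr$start], end_day = wd[wr$end])
    }
  }
  if (is.null(best)) {
    stop(sprintf(
      "year %d: no window of length %d with >= %.0f%% coverage ends in [%s, %s]",
      year, L, 100 * min_coverage,
      format(as.Date(end_lo, origin = "1970-01-01")),
      format(as.Date(end_hi, origin = "1970-01-01"))))
  }
  structure(list(year = year, stt = best_rise, window_length = L,
                 window_end_date = as.Date(best$end, origin = "1970-01-01"),
                 rise_start_date = as.Date(best$start_day, origin = "1970-01-01"),
                 rise_end_date = as.Date(best$end_day, origin = "1970-01-01")),
            class = "trigger_result")
}

#' @export
print.trigger_result <- function(x, ...) {
  cat(sprintf("<trigger_result> %d: STT = %.3f degC (L = %d, window end %s, rise %s -> %s)\n",
              x$year, x$stt, x$window_length, format(x$window_end_date),
              format(x$rise_start_date), format(x$rise_end_date)))
  invisible(x)
}

#' Per-year STT table
#'
#' Applies [compute_stt()] to each requested year and returns a data
#' frame. Years whose spring interval lacks coverage yield `NA` with a
#' warning rather than an error.
#'
#' @inheritParams compute_stt
#' @param years integer vector of years; default every complete year in
#'   `sst`.
#' @return Data frame with columns `year`, `stt`, `window_end_date`,
#'   `rise_start_date`, `rise_end_date`.
#' @export
stt_by_year <- function(sst, years = NULL, L = 28L, season = season_spec(),
                        min_coverage = 0.8,
                        method = c("pairwise", "endpoints")) {
  method <- match.arg(method)
  if (is.null(years)) years <- sort(unique(series_years(sst)))
  rows <- lapply(years, function(y) {
    r <- tryCatch(compute_stt(sst, y, L, season, min_coverage, method),
                  error = function(e) {
                    warning(conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (is.null(r)) {
      data.frame(year = y, stt = NA_real_,
                 window_end_date = as.Date(NA), rise_start_date = as.Date(NA),
                 rise_end_date = as.Date(NA))
    } else {
      data.frame(year = r$year, stt = r$stt,
                 window_end_date = r$window_end_date,
                 rise_start_date = r$rise_start_date,
                 rise_end_date = r$rise_end_date)
    }
  })
  do.call(rbind, rows)
}

#' Peak egg abundance within a seasonal interval
#'
#' Maximum observed single-tow count among the collections falling inside
#' the interval for the given year; ties are broken by the earliest date.
#'
#' @param eggs a [sample_series()].
#' @param year calendar year.
#' @param interval list with `(month, day)` elements `start` and `end`;
#'   default the summer interval of `season`.
#' @param season a [season_spec()] supplying the default interval.
#' @return List with `peak` (eggs/tow) and `peak_date`.
#' @export
peak_eggs <- function(eggs, year, interval = NULL, season = season_spec()) {
  stopifnot(inherits(eggs, "sample_series"))
  year <- as.integer(year)
  if (is.null(interval)) {
    iv <- season_interval(season, "summer", year)
  } else {
    iv <- c(resolve_md(as.integer(interval$start), year),
            resolve_md(as.integer(interval$end), year))
  }
  sel <- eggs$date >= iv[1L] & eggs$date <= iv[2L]
  if (!any(sel)) {
    stop(sprintf("year %d: no egg collections in [%s, %s]",
                 year, format(iv[1L]), format(iv[2L])))
  }
  v <- eggs$value[sel]
  d <- eggs$date[sel]
  i <- which(v == max(v))[1L]  # dates sorted, so first hit = earliest
  list(peak = v[i], peak_date = d[i])
}

#' Fit the linear trigger-to-peak model
#'
#' Ordinary least squares of per-year peak egg abundance on per-year STT,
#' with the Pearson correlation between the two.
#'
#' @param stts numeric vector of per-year STT values (degrees C).
#' @param peaks numeric vector of per-year peak eggs (same length).
#' @return A list of class `trigger_model`: `slope` (eggs/tow per degree
#'   C), `intercept` (eggs/tow), `rho`, `n`.
#' @export
fit_trigger_model <- function(stts, peaks) {
  stts <- as.numeric(stts)
  peaks <- as.numeric(peaks)
  if (length(stts) != length(peaks)) stop("stts and peaks differ in length")
  keep <- is.finite(stts) & is.finite(peaks)
  stts <- stts[keep]
  peaks <- peaks[keep]
  if (length(stts) < 3L) stop("need at least 3 complete years to fit")
  if (sd(stts) == 0) stop("zero variance in STT values: slope/rho undefined")
  slope <- cov(stts, peaks) / var(stts)
  intercept <- mean(peaks) - slope * mean(stts)
  rho <- if (sd(peaks) == 0) {
    stop("zero variance in peaks: rho undefined")
  } else {
    cor(stts, peaks)
  }
  structure(list(slope = slope, intercept = intercept, rho = rho,
                 n = length(stts)),
            class = "trigger_model")
}

#' @export
print.trigger_model <- function(x, ...) {
  cat(sprintf("<trigger_model> peak = %.2f + %.2f * STT (rho = %.3f, n = %d)\n",
              x$intercept, x$slope, x$rho, x$n))
  invisible(x)
}

#' Predict a peak from a fitted trigger model
#'
#' @param model a [fit_trigger_model()] result.
#' @param stt STT value(s) in degrees C.
#' @return Predicted peak eggs per tow (may be negative; reported as-is).
#' @export
predict_peak <- function(model, stt) {
  stopifnot(inherits(model, "trigger_model"))
  stt <- as.numeric(stt)
  if (any(!is.finite(stt))) stop("stt must be finite")
  out <- model$intercept + model$slope * stt
  if (any(out < 0)) {
    message("predicted peak below zero; reporting the raw linear value")
  }
  out
}

#' Shannon diversity (base e)
#'
#' `H = -sum(p_i * log(p_i))` over the positive counts, with
#' `p_i = count_i / sum(counts)`. Used for the species composition of
#' peak-abundance samples.
#'
#' @param counts nonnegative per-species counts, at least one positive.
#' @return Diversity in nats.
#' @examples
#' shannon_diversity(c(5, 5, 5)) # log(3)
#' @export
shannon_diversity <- function(counts) {
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be nonnegative")
  tot <- sum(counts)
  if (tot <= 0) stop("at least one count must be positive")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}
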