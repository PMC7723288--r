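#' Read a sea-surface temperature CSV
#'
#' Two dialects are supported. `"daily"` expects columns `date,temp_c` with
#' one row per day and ISO dates. `"raw_log"` expects `timestamp,temp_c`
#' with sub-daily (e.g. every 5-10 minutes) readings; all readings sharing a
#' calendar date are averaged arithmetically into one daily value. The
#' calendar date is taken from the timestamp text as written -- no timezone
#' arithmetic is applied (instrument logs are assumed local).
#'
#' @param path CSV file path.
#' @param dialect `"daily"` or `"raw_log"`.
#' @return A [daily_series()].
#' @export
read_sst <- function(path, dialect = c("daily", "raw_log")) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) stop("empty SST file: ", path)
  need <- if (dialect == "daily") c("date", "temp_c") else
    c("timestamp", "temp_c")
  if (!all(need %in% names(df))) {
    stop("SST file must have columns ", paste(need, collapse = ","))
  }
  temp <- suppressWarnings(as.numeric(df$temp_c))
  if (anyNA(temp)) {
    stop("non-numeric temperature in row ", which(is.na(temp))[1L],
         " of ", path)
  }
  if (dialect == "daily") {
    d <- as.Date(df$date, format = "%Y-%m-%d")
    if (anyNA(d)) stop("unparseable date in row ", which(is.na(d))[1L])
    if (anyDuplicated(d)) {
      stop("duplicate date in daily SST file: ", format(d[duplicated(d)][1L]))
    }
    o <- order(d)
    return(daily_series(d[o], temp[o], label = basename(path)))
  }
  # raw_log: calendar date = leading YYYY-MM-DD of the timestamp string
  d <- as.Date(substr(trimws(df$timestamp), 1L, 10L), format = "%Y-%m-%d")
  if (anyNA(d)) stop("unparseable timestamp in row ", which(is.na(d))[1L])
  means <- tapply(temp, as.integer(d), mean)
  dates <- as.Date(as.integer(names(means)), origin = "1970-01-01")
  o <- order(dates)
  daily_series(dates[o], as.numeric(means)[o], label = basename(path))
}

#' Read an egg-collection CSV
#'
#' Expects columns `date,total_eggs` plus any number of per-species count
#' columns. Species row sums may not exceed `total_eggs`.
#'
#' @param path CSV file path.
#' @return A [sample_series()].
#' @export
read_eggs <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) stop("empty egg file: ", path)
  if (!all(c("date", "total_eggs") %in% names(df))) {
    stop("egg file must have columns date,total_eggs")
  }
  d <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(d)) stop("unparseable date in row ", which(is.na(d))[1L],
                     " of ", path)
  v <- suppressWarnings(as.numeric(df$total_eggs))
  if (anyNA(v)) stop("non-numeric egg count in row ", which(is.na(v))[1L])
  if (any(v < 0)) stop("negative egg count in row ", which(v < 0)[1L])
  sp_cols <- setdiff(names(df), c("date", "total_eggs"))
  o <- order(d)
  sp <- NULL
  if (length(sp_cols)) {
    sp <- lapply(df[sp_cols], function(col) {
      x <- suppressWarnings(as.numeric(col))
      if (anyNA(x)) stop("non-numeric species count in row ",
                         which(is.na(x))[1L])
      x
    })
    sp <- as.data.frame(sp)[o, , drop = FALSE]
  }
  sample_series(d[o], v[o], species_counts = sp)
}

#' Centered moving average of a daily series
#'
#' The smoothed value at day `t` is the mean of the available values in the
#' symmetric window `[t - (width-1)/2, t + (width-1)/2]`. The output covers
#' every calendar day in the input's range for which at least 50% of the
#' window days carry a value; other days are absent. `width = 1` returns the
#' input unchanged.
#'
#' @param series a [daily_series()].
#' @param width odd positive window width in days.
#' @param alignment only `"centered"` is supported.
#' @return A [daily_series()] of smoothed values.
#' @export
moving_average <- function(series, width, alignment = "centered") {
  stopifnot(inherits(series, "daily_series"))
  alignment <- match.arg(alignment, "centered")
  width <- as.integer(width)
  if (length(width) != 1L || is.na(width) || width < 1L || width %% 2L == 0L) {
    stop("`width` must be an odd positive integer")
  }
  if (width == 1L) return(series)
  h <- (width - 1L) %/% 2L
  d0 <- as.integer(min(series$date))
  d1 <- as.integer(max(series$date))
  n <- d1 - d0 + 1L
  val <- rep(0, n)
  has <- rep(0L, n)
  idx <- as.integer(series$date) - d0 + 1L
  val[idx] <- series$value
  has[idx] <- 1L
  csum <- c(0, cumsum(val))
  ccnt <- c(0L, cumsum(has))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  cnt <- ccnt[hi + 1L] - ccnt[lo]
  sm <- (csum[hi + 1L] - csum[lo]) / cnt
  keep <- cnt / width >= 0.5
  daily_series(as.Date(d0 - 1L + which(keep), origin = "1970-01-01"),
               sm[keep],
               label = sprintf("%s (ma%d)", attr(series, "label"), width))
}
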