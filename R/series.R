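#' Daily time series container
#'
#' A `daily_series` is a data frame with one row per calendar day on which a
#' measurement exists: column `date` (class `Date`, strictly increasing, at
#' most one row per day) and column `value` (numeric, degrees C for sea
#' surface temperature). Missing days are simply absent -- they are never
#' filled or interpolated implicitly.
#'
#' @param dates `Date` vector (or ISO-8601 strings), strictly increasing.
#' @param values numeric vector, same length as `dates`.
#' @param label free-text description stored as an attribute.
#' @return A data frame of class `daily_series`.
#' @examples
#' daily_series(as.Date("2016-04-01") + 0:2, c(15.2, 15.4, 15.1), "sst")
#' @export
daily_series <- function(dates, values, label = "") {
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values)) {
    stop("`dates` and `values` must have the same length")
  }
  if (anyNA(dates)) stop("unparseable date in daily series")
  if (anyNA(values)) stop("missing/non-numeric value in daily series")
  if (length(dates) > 1L && any(diff(as.integer(dates)) <= 0L)) {
    stop("dates must be strictly increasing (at most one value per date)")
  }
  out <- data.frame(date = dates, value = values)
  attr(out, "label") <- as.character(label)[1L]
  class(out) <- c("daily_series", "data.frame")
  out
}

#' Irregular sample series container
#'
#' A `sample_series` holds irregularly dated tow collections: column `date`
#' (strictly increasing), column `value` (eggs per tow, nonnegative), and
#' optionally one nonnegative integer column per species. When species
#' columns are present their row sums may not exceed `value` (unidentified
#' eggs are allowed).
#'
#' @param dates `Date` vector (or ISO strings), strictly increasing.
#' @param values nonnegative numeric vector of total eggs per tow.
#' @param species_counts optional data frame / named list of per-species
#'   nonnegative integer counts.
#' @return A data frame of class `sample_series`; species column names are
#'   recorded in the `"species"` attribute.
#' @export
sample_series <- function(dates, values, species_counts = NULL) {
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values)) {
    stop("`dates` and `values` must have the same length")
  }
  if (anyNA(dates)) stop("unparseable date in sample series")
  if (anyNA(values) || any(values < 0)) {
    stop("egg counts must be nonnegative numbers")
  }
  if (length(dates) > 1L && any(diff(as.integer(dates)) <= 0L)) {
    stop("collection dates must be strictly increasing")
  }
  out <- data.frame(date = dates, value = values)
  species <- character(0)
  if (!is.null(species_counts)) {
    species_counts <- as.data.frame(species_counts)
    if (nrow(species_counts) != length(dates)) {
      stop("species counts must have one row per collection")
    }
    for (nm in names(species_counts)) {
      cnt <- species_counts[[nm]]
      if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt))) {
        stop("species counts must be nonnegative integers (column ", nm, ")")
      }
      out[[nm]] <- as.numeric(cnt)
    }
    species <- names(species_counts)
    ssum <- rowSums(out[, species, drop = FALSE])
    bad <- which(ssum > out$value + 1e-9)
    if (length(bad)) {
      stop("species counts exceed total eggs in row ", bad[1L])
    }
  }
  attr(out, "species") <- species
  class(out) <- c("sample_series", "data.frame")
  out
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> %s: %d days, %s .. %s\n",
              attr(x, "label"), nrow(x),
              format(min(x$date)), format(max(x$date))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' @export
print.sample_series <- function(x, ...) {
  cat(sprintf("<sample_series> %d collections, %s .. %s\n",
              nrow(x), format(min(x$date)), format(max(x$date))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

# year labels as integers for a Date vector
series_years <- function(x) as.integer(format(x$date, "%Y"))

#' Write a daily series to CSV (daily dialect)
#'
#' Values are written with 17 significant digits so that a write/read cycle
#' through [read_sst()] is bit-identical.
#'
#' @param series a [daily_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sst <- function(series, path) {
  stopifnot(inherits(series, "daily_series"))
  df <- data.frame(date = format(series$date, "%Y-%m-%d"),
                   temp_c = sprintf("%.17g", series$value))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write a sample series to CSV
#'
#' @param series a [sample_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eggs <- function(series, path) {
  stopifnot(inherits(series, "sample_series"))
  df <- data.frame(date = format(series$date, "%Y-%m-%d"),
                   total_eggs = sprintf("%.17g", series$value))
  for (nm in attr(series, "species")) df[[nm]] <- series[[nm]]
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
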