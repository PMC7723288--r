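#' Season boundary specification
#'
#' Holds the (month, day) boundaries that define the spring trigger
#' interval, the summer egg-peak interval and the winter averaging
#' interval. Boundaries are resolved per calendar year; winter spans the
#' year boundary (December of the preceding year through February), and
#' Feb 29 resolves to the last day of February in non-leap years (so
#' Feb 29, when it exists, belongs to winter).
#'
#' @param spring_start,spring_end `(month, day)` pairs bounding the spring
#'   interval traversed by the trigger window's last day. Default
#'   Apr 1 - Jun 18.
#' @param summer_start,summer_end `(month, day)` pairs bounding the summer
#'   egg-peak interval. Default Jun 1 - Aug 31.
#' @param winter_start,winter_end `(month, day)` pairs bounding winter;
#'   `winter_start` falls in the preceding calendar year. Default
#'   Dec 1 - end of February.
#' @return A list of class `season_spec`.
#' @export
season_spec <- function(spring_start = c(4L, 1L), spring_end = c(6L, 18L),
                        summer_start = c(6L, 1L), summer_end = c(8L, 31L),
                        winter_start = c(12L, 1L), winter_end = c(2L, 29L)) {
  spec <- list(spring_start = as.integer(spring_start),
               spring_end = as.integer(spring_end),
               summer_start = as.integer(summer_start),
               summer_end = as.integer(summer_end),
               winter_start = as.integer(winter_start),
               winter_end = as.integer(winter_end))
  for (nm in names(spec)) {
    md <- spec[[nm]]
    if (length(md) != 2L || anyNA(md) || md[1L] < 1L || md[1L] > 12L ||
        md[2L] < 1L || md[2L] > 31L) {
      stop("invalid (month, day) pair for ", nm)
    }
  }
  if (resolve_md(spec$spring_start, 2015L) > resolve_md(spec$spring_end, 2015L))
    stop("spring_start must not be after spring_end")
  if (resolve_md(spec$summer_start, 2015L) > resolve_md(spec$summer_end, 2015L))
    stop("summer_start must not be after summer_end")
  class(spec) <- "season_spec"
  spec
}

# Resolve a (month, day) pair in a given year; days past the month's end
# clamp to the last day of that month (Feb 29 -> Feb 28 in non-leap years).
resolve_md <- function(md, year) {
  last <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  maxd <- ifelse(md[1L] == 2L & leap, 29L, last[md[1L]])
  as.Date(sprintf("%04d-%02d-%02d", year, md[1L], min(md[2L], maxd)))
}

# Interval of dates for a named season in a given year. Winter of year y
# runs from winter_start of y-1 through winter_end of y.
season_interval <- function(season, which, year) {
  switch(which,
    spring = c(resolve_md(season$spring_start, year),
               resolve_md(season$spring_end, year)),
    summer = c(resolve_md(season$summer_start, year),
               resolve_md(season$summer_end, year)),
    winter = c(resolve_md(season$winter_start, year - 1L),
               resolve_md(season$winter_end, year)),
    stop("unknown season: ", which))
}
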