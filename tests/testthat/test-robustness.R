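# Constructed series where peaks are an exact linear function of the
# per-year event magnitude: flat-background SST with one short triangular
# event per year, one summer collection per year carrying the peak.
linear_fixture <- function(mags = c(1.5, 2, 2.5, 3, 3.5, 4, 4.5),
                           seed = 1) {
  # events mid-spring and peaks mid-summer, well clear of every audited
  # season boundary
  p <- noise_free_params(seed = seed, n_years = length(mags),
                         event_magnitudes = mags, event_duration = 5,
                         event_day_window = c(105, 125),
                         peak_day_window = c(190, 215))
  sst <- generate_sst(p)
  years <- 2013:(2012 + length(mags))
  eggs <- sample_series(as.Date(sprintf("%d-07-15", years)),
                        100 + 150 * mags)
  list(sst = sst, eggs = eggs, mags = mags, years = years)
}

test_that("window-width scan is flat at rho = 1 on exactly coupled data", {
  fx <- linear_fixture()
  sc <- window_width_scan(fx$sst, fx$eggs, L_grid = c(10, 14, 21, 28, 35))
  expect_true(all(sc$valid))
  expect_equal(sc$rho, rep(1, 5), tolerance = 1e-9)
  expect_equal(sc$n, rep(7L, 5))
})

test_that("a single-L scan reproduces the direct model fit", {
  p <- synthetic_params(seed = 909)
  st <- generate_study(p)
  sc <- window_width_scan(st$sst, st$eggs, L_grid = 28)
  tab <- stt_by_year(st$sst)
  peaks <- vapply(2013:2019, function(y) peak_eggs(st$eggs, y)$peak,
                  numeric(1))
  m <- fit_trigger_model(tab$stt, peaks)
  expect_equal(sc$rho, m$rho)
  expect_equal(sc$n, m$n)
})

test_that("boundary scan's (0,0) cell equals the unshifted analysis", {
  p <- synthetic_params(seed = 910)
  st <- generate_study(p)
  bs <- boundary_scan(st$sst, st$eggs, spring_end_offsets = c(-7, 0, 7),
                      summer_start_offsets = c(-7, 0, 7), L = 28)
  base <- window_width_scan(st$sst, st$eggs, L_grid = 28)
  cell <- bs[bs$spring_end_offset == 0 & bs$summer_start_offset == 0, ]
  expect_equal(cell$rho, base$rho)
  expect_equal(cell$n, base$n)
})

test_that("boundary surface is flat for well-separated events and peaks", {
  fx <- linear_fixture()
  bs <- boundary_scan(fx$sst, fx$eggs, spring_end_offsets = seq(-7, 7, 7),
                      summer_start_offsets = seq(-7, 7, 7), L = 28)
  expect_true(all(bs$valid))
  expect_true(max(abs(bs$rho - 1)) <= 0.02)
})

test_that("boundary surface is fragile on null data", {
  spread <- vapply(1:20, function(i) {
    p <- synthetic_params(null_model = TRUE, seed = 6000 + 10 * i)
    st <- generate_study(p)
    bs <- boundary_scan(st$sst, st$eggs,
                        spring_end_offsets = seq(-21, 21, 7),
                        summer_start_offsets = seq(-21, 21, 7), L = 28)
    r <- abs(bs$rho[bs$valid])
    max(r) - min(r)
  }, numeric(1))
  expect_gt(mean(spread >= 0.3), 0.5)
})

test_that("any-time trigger dominates the spring-restricted STT", {
  p <- synthetic_params(seed = 911)
  st <- generate_study(p)
  at <- anytime_trigger_scan(st$sst, st$eggs, L = 28)
  tab <- stt_by_year(st$sst)
  joined <- merge(at$records, tab, by = "year")
  expect_true(all(joined$trigger >= joined$stt - 1e-12))
  expect_error(anytime_trigger_scan(st$sst, st$eggs[st$eggs$date <
                                                    as.Date("2014-01-01"), ]),
               "fewer than 3")
})

test_that("an uncorrelated winter excursion degrades the any-time correlation", {
  fx <- linear_fixture()
  # add a larger winter warm excursion whose alternating magnitudes are
  # exactly uncorrelated with the (monotone) spring event magnitudes
  sst2 <- fx$sst
  winter_mag <- 5 + 0.9 * c(1, -1, 1, -1, 1, -1, 1)
  for (i in seq_along(fx$years)) {
    s0 <- as.Date(sprintf("%d-02-10", fx$years[i]))
    k <- 0:10
    bump <- winter_mag[i] * ifelse(k <= 5, k / 5, (10 - k) / 5)
    idx <- match(s0 + k, sst2$date)
    sst2$value[idx] <- sst2$value[idx] + bump
  }
  spring_rho <- window_width_scan(sst2, fx$eggs, L_grid = 28)$rho
  at <- anytime_trigger_scan(sst2, fx$eggs, L = 28)
  expect_gt(spring_rho, 0.99)
  expect_lt(abs(at$rho), abs(spring_rho) - 0.3)
})

test_that("smoothing at width 1 is the unsmoothed analysis and wide smoothing shrinks the STT", {
  p <- synthetic_params(seed = 912)
  st <- generate_study(p)
  sc <- smoothing_scan(st$sst, st$eggs, widths = c(1, 31), L = 28)
  base <- window_width_scan(st$sst, st$eggs, L_grid = 28)
  expect_equal(sc$rho[sc$width == 1], base$rho)
  stt1 <- stt_by_year(st$sst)$stt
  stt31 <- stt_by_year(moving_average(st$sst, 31))$stt
  expect_true(all(stt31 < stt1))
  expect_error(smoothing_scan(st$sst, st$eggs, widths = c(1, 4)), "odd")
})

test_that("constant SST gives zero STT and invalid correlations at every width", {
  d <- seq(as.Date("2013-01-01"), as.Date("2015-12-31"), 1)
  flat <- daily_series(d, rep(15, length(d)))
  eggs <- sample_series(as.Date(c("2013-07-01", "2014-07-01", "2015-07-01")),
                        c(100, 300, 200))
  sc <- smoothing_scan(flat, eggs, widths = c(1, 7), L = 28)
  expect_true(all(!sc$valid))
  expect_true(all(is.na(sc$rho)))
})

test_that("lagged cross-correlation recovers an exact 30-day lag", {
  d <- seq(as.Date("2013-01-01"), as.Date("2016-12-31"), 1)
  set.seed(13)
  sst <- daily_series(d, 15 + as.numeric(arima.sim(list(ar = 0.9),
                                                   length(d))))
  lag_idx <- seq_along(d) - 30
  ok <- lag_idx >= 1
  eggs <- sample_series(d[ok], pmax(0, 50 + 10 * sst$value[lag_idx[ok]]))
  sc <- lagged_crosscorr(sst, eggs, delays = c(0, 15, 30, 60),
                         match_tolerance = 0)
  expect_equal(sc$rho[sc$delay == 30], 1, tolerance = 1e-9)
  expect_true(all(sc$rho[sc$delay != 30] < 1 - 1e-6))
})

test_that("no pairing within tolerance marks delays invalid", {
  d <- seq(as.Date("2013-01-01"), as.Date("2014-12-31"), 1)
  sst <- daily_series(d, rnorm(length(d), 15))
  # collections only in July, so winter days + small delays never pair
  eggs <- sample_series(as.Date(c("2013-07-01", "2013-07-05", "2014-07-02")),
                        c(10, 20, 30))
  sc <- lagged_crosscorr(sst, eggs, delays = c(0, 5), match_tolerance = 0)
  expect_true(all(!sc$valid))
})

test_that("seasonal aggregate correlation is exact on constructed averages", {
  d <- seq(as.Date("2012-12-01"), as.Date("2016-12-31"), 1)
  winter_means <- c(14, 15, 16, 17)
  v <- rep(15, length(d))
  for (i in seq_along(winter_means)) {
    y <- 2012 + i
    sel <- d >= as.Date(sprintf("%d-12-01", y - 1)) &
      d < as.Date(sprintf("%d-03-01", y))
    v[sel] <- winter_means[i]
  }
  sst <- daily_series(d, v)
  egg_dates <- as.Date(sprintf("%d-05-15", 2013:2016))
  eggs <- sample_series(egg_dates, 100 - 10 * winter_means + 150)
  sc <- seasonal_aggregate_corr(sst, eggs)
  expect_equal(sc$rho, -1, tolerance = 1e-9)
  expect_equal(sc$n, 4L)

  flat <- daily_series(d, rep(15, length(d)))
  expect_error(seasonal_aggregate_corr(flat, eggs), "zero variance")
})

test_that("a negative winter-to-eggs coupling is recovered with the right sign", {
  neg <- vapply(1:20, function(i) {
    # constant latent peaks, so the only year-to-year egg signal is the
    # winter-driven scaling imposed below
    p <- synthetic_params(seed = 7000 + 10 * i, coupling_slope = 0,
                          peak_noise_sd = 0)
    st <- generate_study(p)
    winter <- vapply(2013:2019, function(y) {
      sel <- st$sst$date >= as.Date(sprintf("%d-12-01", y - 1)) &
        st$sst$date < as.Date(sprintf("%d-03-01", y))
      mean(st$sst$value[sel])
    }, numeric(1))
    eggs <- st$eggs
    yr <- as.integer(format(eggs$date, "%Y"))
    scale <- pmax(0.1, 1 - 1.5 * (winter - mean(winter)))
    eggs$value <- round(eggs$value * scale[yr - 2012])
    seasonal_aggregate_corr(st$sst, eggs)$rho < 0
  }, logical(1))
  expect_gte(mean(neg), 0.9)
})

test_that("annual variable matrix is symmetric with unit diagonal", {
  p <- synthetic_params(seed = 913)
  st <- generate_study(p)
  m <- annual_variable_matrix(st$sst, st$eggs)
  expect_equal(diag(m), stats::setNames(rep(1, 4), colnames(m)))
  expect_lt(max(abs(m - t(m))), 1e-12)
  expect_gt(m["peak_summer_eggs", "mean_summer_eggs"], 0)
  expect_equal(attr(m, "n"), 7L)
})
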