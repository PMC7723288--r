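test_that("weekly collections embed from the third collection onward", {
  d <- as.Date("2016-01-01") + seq(0, 7 * 19, 7)
  eggs <- sample_series(d, 10 + seq_along(d))
  covd <- daily_series(seq(min(d), max(d), 1),
                       rnorm(as.integer(max(d) - min(d)) + 1, 15))
  emb <- build_embedding(eggs, covd, lags = c(7, 14), tolerance = 1)
  expect_equal(nrow(emb), length(d) - 2L)
  expect_equal(emb$date, d[-(1:2)])
  expect_equal(emb$lag_7, eggs$value[match(emb$date - 7, eggs$date)])
})

test_that("lag windows admit collections 6-8 and 13-15 days prior", {
  d0 <- as.Date("2016-03-01")
  eggs <- sample_series(d0 + c(0, 6, 14, 21), c(5, 10, 20, 40))
  covd <- daily_series(d0 + 0:21, rep(16, 22))
  emb <- build_embedding(eggs, covd, lags = c(7, 14), tolerance = 1)
  # day 14: lag-7 matched at day 6 (8 days back), lag-14 at day 0
  row14 <- emb[emb$date == d0 + 14, ]
  expect_equal(nrow(row14), 1L)
  expect_equal(row14$lag_7, 10)
  expect_equal(row14$lag_14, 5)
})

test_that("a 10-day gap removes the affected target dates", {
  d <- as.Date("2016-01-01") + c(seq(0, 35, 7), 52, 59, 66, 73)
  eggs <- sample_series(d, rpois(length(d), 30) + 1)
  covd <- daily_series(seq(min(d), max(d), 1),
                       rnorm(as.integer(max(d) - min(d)) + 1, 15))
  emb <- build_embedding(eggs, covd, lags = c(7, 14), tolerance = 1)
  # day 52 lacks a collection 6-8 days prior (gap 35 -> 52)
  expect_false((as.Date("2016-01-01") + 52) %in% emb$date)
  expect_true((as.Date("2016-01-01") + 73) %in% emb$date)
})

test_that("nearest-to-nominal wins inside a tolerance window, earlier on ties", {
  d0 <- as.Date("2016-05-01")
  # target t = day 20; lag 7 window is day 12-14; days 12 and 14 both exist
  eggs <- sample_series(d0 + c(0, 6, 12, 14, 20), c(1, 2, 3, 4, 5))
  covd <- daily_series(d0 + 0:20, rep(15, 21))
  emb <- build_embedding(eggs, covd, lags = c(7, 14), tolerance = 1)
  row <- emb[emb$date == d0 + 20, ]
  expect_equal(row$lag_7, 3)  # day 13 nominal; 12 and 14 tie, earlier wins
  expect_equal(row$lag_14, 2) # day 6 exactly
})

test_that("the empty-embedding error reports which lag failed", {
  d <- as.Date("2016-01-01") + seq(0, 90, 10)
  eggs <- sample_series(d, rep(5, length(d)))
  covd <- daily_series(seq(min(d), max(d), 1),
                       rep(15, as.integer(max(d) - min(d)) + 1))
  expect_error(build_embedding(eggs, covd, lags = c(7, 14), tolerance = 1),
               "lag_7")
})

test_that("S-map at theta 0 equals leave-one-out global OLS", {
  set.seed(500)
  for (i in 1:3) {
    x <- gen_logistic(60, noise_sd = 0.02)
    emb <- daily_embedding(x)
    sm <- smap_forecast(emb, theta = 0)
    expect_equal(sm$predictions$predicted, oracle_loo_ols(emb),
                 tolerance = 1e-8)
  }
})

test_that("S-map distinguishes a chaotic map from a linear process", {
  set.seed(501)
  x <- gen_logistic(300, noise_sd = 0.01)
  sc <- theta_scan(daily_embedding(x))
  expect_true(attr(sc, "nonlinear"))
  expect_gt(attr(sc, "delta_rho"), 0.05)

  ar <- 50 + as.numeric(stats::arima.sim(list(ar = 0.8), 300))
  sc2 <- theta_scan(daily_embedding(ar))
  expect_lte(attr(sc2, "delta_rho"), 0.01)
  expect_false(attr(sc2, "nonlinear"))
})

test_that("theta_scan enforces its grid contract", {
  set.seed(502)
  emb <- daily_embedding(gen_logistic(80))
  expect_error(theta_scan(emb, thetas = c(0.5, 1)), "contain 0")
  single <- theta_scan(emb, thetas = 0)
  expect_equal(nrow(single), 1L)
  expect_equal(single$rho, smap_forecast(emb, 0)$rho)
  const <- daily_embedding(rep(4, 60))
  expect_error(theta_scan(const), "constant")
})

test_that("cross-mapping a covariate equal to a coordinate is near-perfect", {
  set.seed(503)
  x <- gen_logistic(200)
  emb <- daily_embedding(x, covariate = x)  # cov identical to x0
  cc <- ccm(emb, library_sizes = c(10, 30, 50), k = 4, proximity = 90,
            n_draws = 10, seed = 99)
  # a k-neighbor average is exact only in the large-library limit
  expect_true(all(cc$mean_rho > 0.85))
  expect_true(all(diff(cc$mean_rho) > 0))
  expect_gt(cc$mean_rho[nrow(cc)], 0.99)
})

test_that("CCM is reproducible draw-for-draw and invariant to affine covariates", {
  set.seed(504)
  pair <- gen_coupled_logistic(200)
  d <- as.Date("2015-01-01") + 0:199
  emb <- build_embedding(sample_series(d, pair$response),
                         daily_series(d, pair$driver),
                         lags = c(1, 2), tolerance = 0)
  a <- ccm(emb, c(10, 40, 70), n_draws = 1, seed = 7)
  b <- ccm(emb, c(10, 40, 70), n_draws = 1, seed = 7)
  expect_identical(attr(a, "draws"), attr(b, "draws"))

  emb2 <- emb
  emb2$cov <- 3 * emb2$cov - 10
  c2 <- ccm(emb2, c(10, 40, 70), n_draws = 5, seed = 7)
  c1 <- ccm(emb, c(10, 40, 70), n_draws = 5, seed = 7)
  expect_equal(c2$mean_rho, c1$mean_rho, tolerance = 1e-12)
  expect_error(ccm(emb, c(10, 40, 70)), "seed")
})

test_that("widening the proximity constraint only enlarges candidate pools", {
  set.seed(505)
  x <- gen_logistic(150)
  emb <- daily_embedding(x)
  dates <- emb$date
  near <- springtrigger:::candidate_pools(dates, 30)
  far <- springtrigger:::candidate_pools(dates, 90)
  expect_true(all(lengths(far) >= lengths(near)))
  expect_true(all(mapply(function(a, b) all(a %in% b), near, far)))
})

test_that("convergence summary flags rising but not flat skill curves", {
  rising <- structure(
    data.frame(lib_size = c(10, 40, 80), mean_rho = c(0.1, 0.4, 0.6),
               sd_rho = 0.02, n_targets = 100L),
    class = c("ccm_result", "data.frame"))
  cs <- convergence_summary(rising)
  expect_true(cs$converged)
  expect_equal(cs$rho_max_lib, 0.6)
  flat <- rising
  flat$mean_rho <- c(0.01, 0, 0.02)
  expect_false(convergence_summary(flat)$converged)
})
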