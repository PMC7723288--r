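# Empirical dynamic modeling for irregularly sampled series: lag-tolerance
# delay embedding, leave-one-out S-map forecasting with a theta scan, and
# convergent cross mapping with random libraries under a calendar-proximity
# neighbor constraint.

#' Build a lag-tolerance delay embedding from irregular collections
#'
#' One row is produced per collection date `t` for which (a) the daily
#' covariate has a value at `t`, and (b) for every nominal lag `tau` a
#' collection exists whose date lies within `tolerance` days of `t - tau`.
#' When several collections fall inside a tolerance window, the one
#' nearest the nominal lag is used (ties to the earlier date). With the
#' defaults (lags 7 and 14 days, tolerance 1) this reproduces the
#' filtering of a weekly-lag, 3-dimensional embedding: collections at
#' `t`, 6-8 days prior, and 13-15 days prior.
#'
#' @param eggs a [sample_series()] of the embedded observable.
#' @param covariate a [daily_series()] (e.g. daily SST) aligned by date.
#' @param lags nominal lags in days (default `c(7, 14)`; embedding
#'   dimension is `length(lags) + 1`).
#' @param tolerance allowed deviation from each nominal lag, days.
#' @return A data frame of class `embedding` with columns `date`, `x0`,
#'   one `lag_<tau>` column per lag, and `cov`; attributes `lags`,
#'   `tolerance`, `E`.
#' @export
build_embedding <- function(eggs, covariate, lags = c(7L, 14L),
                            tolerance = 1L) {
  stopifnot(inherits(eggs, "sample_series"),
            inherits(covariate, "daily_series"))
  lags <- as.integer(lags)
  tolerance <- as.integer(tolerance)
  if (tolerance < 0L) stop("lag tolerance must be >= 0")
  if (length(lags) < 1L || any(lags < 1L)) stop("lags must be >= 1 day")
  ed <- as.integer(eggs$date)
  ev <- eggs$value
  cov_idx <- match(ed, as.integer(covariate$date))
  fail <- c(covariate = 0L, stats::setNames(integer(length(lags)),
                                            paste0("lag_", lags)))
  rows <- vector("list", length(ed))
  for (i in seq_along(ed)) {
    if (is.na(cov_idx[i])) {
      fail["covariate"] <- fail["covariate"] + 1L
      next
    }
    coordv <- numeric(length(lags))
    ok <- TRUE
    for (l in seq_along(lags)) {
      target <- ed[i] - lags[l]
      dist <- abs(ed - target)
      cand <- which(dist <= tolerance)
      if (!length(cand)) {
        fail[paste0("lag_", lags[l])] <- fail[paste0("lag_", lags[l])] + 1L
        ok <- FALSE
        break
      }
      best <- cand[order(dist[cand], ed[cand])][1L]  # nearest, tie earlier
      coordv[l] <- ev[best]
    }
    if (!ok) next
    rows[[i]] <- c(ed[i], ev[i], coordv, covariate$value[cov_idx[i]])
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    stop("empty embedding: of ", length(ed), " candidate dates, failures were ",
         paste(names(fail), fail, sep = "=", collapse = ", "))
  }
  m <- do.call(rbind, rows)
  out <- data.frame(date = as.Date(m[, 1L], origin = "1970-01-01"),
                    x0 = m[, 2L])
  for (l in seq_along(lags)) out[[paste0("lag_", lags[l])]] <- m[, 2L + l]
  out$cov <- m[, ncol(m)]
  attr(out, "lags") <- lags
  attr(out, "tolerance") <- tolerance
  attr(out, "E") <- length(lags) + 1L
  class(out) <- c("embedding", "data.frame")
  out
}

embedding_lag_cols <- function(embedding) {
  paste0("lag_", attr(embedding, "lags"))
}

# Full E-dimensional state coordinates (own value + lagged values).
embedding_coords <- function(embedding) {
  as.matrix(embedding[, c("x0", embedding_lag_cols(embedding)), drop = FALSE])
}

#' S-map leave-one-out forecast at a fixed nonlinearity
#'
#' For each embedding row the remaining rows (outside `exclusion` days of
#' the target date) are weighted by `w_i = exp(-theta * d_i / dbar)`,
#' where `d_i` is the Euclidean distance to the target in the lagged
#' coordinates and `dbar` their mean, and a locally weighted linear map
#' from the lagged coordinates to the row's own-time value is solved (the
#' sequential locally weighted global linear map convention: rows of the
#' design are scaled by `w`). `theta = 0` weights all rows equally and so
#' reduces to leave-one-out global linear regression. Singular weighted
#' systems fall back to the minimum-norm solution via SVD.
#'
#' @param embedding a [build_embedding()] result.
#' @param theta nonlinearity parameter, `>= 0`.
#' @param exclusion Theiler-style exclusion radius in days; rows within
#'   this many days of the target date are left out (0 = the target's
#'   own date only).
#' @return A list: `rho` (Pearson correlation of predictions vs
#'   observations), `predictions` data frame, `n`, `theta`,
#'   `n_singular` (count of rank-deficient local fits).
#' @export
smap_forecast <- function(embedding, theta, exclusion = 0L) {
  stopifnot(inherits(embedding, "embedding"))
  if (!is.finite(theta) || theta < 0) stop("theta must be >= 0")
  X <- as.matrix(embedding[, embedding_lag_cols(embedding), drop = FALSE])
  y <- embedding$x0
  n <- nrow(X)
  E <- attr(embedding, "E")
  if (n < E + 2L) stop("need at least E + 2 embedding rows")
  if (sd(y) == 0) stop("constant target values: forecast skill undefined")
  dates <- as.numeric(embedding$date)
  D <- as.matrix(stats::dist(X))
  preds <- numeric(n)
  n_singular <- 0L
  p <- ncol(X) + 1L
  for (i in seq_len(n)) {
    keep <- abs(dates - dates[i]) > exclusion
    if (sum(keep) < p) stop("exclusion radius leaves too few rows")
    dvec <- D[i, keep]
    dbar <- mean(dvec)
    if (dbar == 0) stop("degenerate embedding: all states identical")
    w <- exp(-theta * dvec / dbar)
    A <- cbind(1, X[keep, , drop = FALSE]) * w
    b <- y[keep] * w
    fit <- stats::.lm.fit(A, b)
    if (fit$rank < p) {
      n_singular <- n_singular + 1L
      sv <- svd(A)
      pos <- sv$d > max(sv$d) * 1e-10
      co <- sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
      co <- as.numeric(co)
    } else {
      co <- fit$coefficients
    }
    preds[i] <- sum(c(1, X[i, ]) * co)
  }
  rho <- if (sd(preds) == 0) NA_real_ else cor(preds, y)
  list(rho = rho,
       predictions = data.frame(date = embedding$date, observed = y,
                                predicted = preds),
       n = n, theta = theta, n_singular = n_singular)
}

#' S-map nonlinearity scan over theta
#'
#' Runs [smap_forecast()] at each `theta` and flags the series as
#' nonlinear when the best skill exceeds the linear (`theta = 0`) skill
#' by more than `nonlinear_margin`. Improvement of forecast skill with
#' `theta > 0` indicates state-dependent (nonlinear) dynamics.
#'
#' @inheritParams smap_forecast
#' @param thetas nonnegative grid, must contain 0.
#' @param nonlinear_margin improvement in rho required to flag
#'   nonlinearity.
#' @return A data frame of class `smap_result` with columns `theta`,
#'   `rho`, `n`; attributes `nonlinear` (flag), `delta_rho`
#'   (max rho - rho at 0), `exclusion`.
#' @export
theta_scan <- function(embedding,
                       thetas = c(0, 0.1, 0.25, 0.5, 0.75, 1, 1.5, 2, 3,
                                  4, 6, 8),
                       exclusion = 0L, nonlinear_margin = 0.02) {
  thetas <- as.numeric(thetas)
  if (!any(thetas == 0)) stop("theta grid must contain 0")
  res <- lapply(thetas, function(th) smap_forecast(embedding, th, exclusion))
  out <- data.frame(theta = thetas,
                    rho = vapply(res, `[[`, numeric(1L), "rho"),
                    n = vapply(res, `[[`, integer(1L), "n"))
  if (all(is.na(out$rho))) {
    stop("no theta produced a defined forecast skill")
  }
  delta <- max(out$rho, na.rm = TRUE) - out$rho[out$theta == 0][1L]
  attr(out, "delta_rho") <- delta
  attr(out, "nonlinear") <- isTRUE(delta > nonlinear_margin)
  attr(out, "exclusion") <- exclusion
  class(out) <- c("smap_result", "data.frame")
  out
}

#' Convergent cross mapping with random libraries
#'
#' Cross-maps from the embedding of the putative response to the
#' covariate (the putative driver): for each target row, a library of
#' each requested size is drawn uniformly without replacement from the
#' target's candidate pool -- the other rows whose dates satisfy the
#' calendar-proximity constraint -- and the `k` nearest library rows in
#' state space predict the target's covariate as an exponentially
#' weighted average (`u_i = exp(-d_i / d_1)`; all-equal weights when
#' `d_1 = 0`). Targets whose pool is smaller than the library size are
#' skipped. One Pearson rho per draw is computed over the predicted
#' targets; the mean and sd over draws are reported per library size.
#' Rising skill with library size ("convergence") indicates that the
#' covariate leaves a causal signature in the embedded dynamics; the
#' proximity constraint prevents shared seasonality from masquerading as
#' that signature.
#'
#' @param embedding a [build_embedding()] result.
#' @param library_sizes strictly increasing library sizes (each `>= k`).
#' @param k number of nearest neighbors (conventionally `E + 1`).
#' @param proximity calendar-proximity radius in days.
#' @param n_draws random library draws per size.
#' @param seed integer seed (mandatory; draws are reproducible
#'   draw-for-draw).
#' @param proximity_mode `"doy"` (circular day-of-year distance, the
#'   default: candidates from any year at a similar seasonal phase) or
#'   `"absolute"` (|date difference|). For multi-year records sampled
#'   every few days, only the seasonal-phase reading yields candidate
#'   pools large enough to support libraries of the conventional 10-80
#'   points.
#' @param weighting `"exponential"` or `"uniform"` neighbor weights.
#' @return A data frame of class `ccm_result` with columns `lib_size`,
#'   `mean_rho`, `sd_rho`, `n_targets`; attributes `n_draws`, `seed`,
#'   `k`, `proximity`, `draws` (the per-draw rho matrix).
#' @export
ccm <- function(embedding, library_sizes = seq(10L, 80L, 5L), k = 4L,
                proximity = 90L, n_draws = 50L, seed,
                proximity_mode = c("doy", "absolute"),
                weighting = c("exponential", "uniform")) {
  stopifnot(inherits(embedding, "embedding"))
  proximity_mode <- match.arg(proximity_mode)
  weighting <- match.arg(weighting)
  if (missing(seed)) stop("a seed is mandatory for reproducible CCM draws")
  library_sizes <- as.integer(library_sizes)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (any(diff(library_sizes) <= 0L) && length(library_sizes) > 1L) {
    stop("library sizes must be strictly increasing")
  }
  if (any(library_sizes < k)) stop("library sizes must be >= k")
  coords <- embedding_coords(embedding)
  n <- nrow(coords)
  pools <- candidate_pools(embedding$date, proximity, proximity_mode)
  pool_sizes <- lengths(pools)
  if (all(pool_sizes < k)) {
    stop("every candidate pool is smaller than k; increase `proximity`")
  }
  set.seed(as.integer(seed))
  res <- ccm_cpp(coords, embedding$cov, pools, library_sizes, k,
                 as.integer(n_draws), weighting == "uniform")
  draws <- res$rho
  out <- data.frame(lib_size = library_sizes,
                    mean_rho = apply(draws, 2L, mean, na.rm = TRUE),
                    sd_rho = apply(draws, 2L, sd, na.rm = TRUE),
                    n_targets = as.integer(res$n_used))
  out$mean_rho[is.nan(out$mean_rho)] <- NA_real_
  attr(out, "n_draws") <- as.integer(n_draws)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "k") <- k
  attr(out, "proximity") <- as.integer(proximity)
  attr(out, "draws") <- draws
  class(out) <- c("ccm_result", "data.frame")
  out
}

# 0-based candidate pools under the calendar-proximity constraint.
candidate_pools <- function(dates, proximity, mode = "absolute") {
  dn <- as.numeric(dates)
  n <- length(dn)
  prox <- as.numeric(proximity)
  if (mode == "absolute") {
    lapply(seq_len(n), function(i) {
      which(abs(dn - dn[i]) <= prox & seq_len(n) != i) - 1L
    })
  } else {
    doy <- as.POSIXlt(dates)$yday + 1
    lapply(seq_len(n), function(i) {
      dd <- abs(doy - doy[i])
      dd <- pmin(dd, 365 - dd)
      which(dd <= prox & seq_len(n) != i) - 1L
    })
  }
}

#' Summarize CCM convergence
#'
#' @param result a [ccm()] result.
#' @param margin required gain in mean rho from the smallest to the
#'   largest library size.
#' @return List with `rho_max_lib` (mean rho at the largest library),
#'   `slope` (trend of mean rho per library point), and `converged`
#'   (`TRUE` when the gain exceeds `margin` and the trend is positive).
#' @export
convergence_summary <- function(result, margin = 0.1) {
  stopifnot(inherits(result, "ccm_result"))
  if (nrow(result) < 3L) stop("need at least 3 library sizes")
  ok <- is.finite(result$mean_rho)
  if (sum(ok) < 3L) stop("fewer than 3 library sizes with defined skill")
  fit <- lm(mean_rho ~ lib_size, data = result[ok, ])
  gain <- result$mean_rho[max(which(ok))] - result$mean_rho[min(which(ok))]
  list(rho_max_lib = result$mean_rho[max(which(ok))],
       slope = unname(coef(fit)[2L]),
       converged = isTRUE(gain >= margin && coef(fit)[2L] > 0))
}
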