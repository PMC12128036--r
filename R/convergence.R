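#' Property timeseries
#'
#' @param times Strictly increasing times, ns.
#' @param values Property values, one per time.
#' @param name Property name.
#' @return A list with class `"property_timeseries"`.
#' @export
property_timeseries <- function(times, values, name = "property") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  structure(list(name = name, times = times, values = values),
            class = "property_timeseries")
}

#' Reduce a per-aggregate property table to system timeseries
#'
#' One series per property: at each time step, the mean of the property across
#' the aggregates coexisting at that step, after excluding aggregates below
#' the reporting threshold. Frames where no aggregate qualifies are dropped
#' (recorded in `dropped_times`).
#'
#' @param table data.frame with columns `time`, `n` and one column per
#'   property (e.g. from [run_isotropic_pipeline()]).
#' @param properties Property column names; defaults to every numeric column
#'   other than `time`, `n`, `aggregate_id`.
#' @param min_n Minimum aggregation number for inclusion.
#' @return Named list of [property_timeseries()], with attribute
#'   `dropped_times`.
#' @export
reduce_aggregate_properties <- function(table, properties = NULL, min_n = 5) {
  stopifnot(is.data.frame(table), all(c("time", "n") %in% names(table)))
  if (is.null(properties)) {
    skip <- c("time", "n", "aggregate_id", "normalized_n", "percolating")
    properties <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], skip)
  }
  keep <- table$n >= min_n
  all_times <- sort(unique(table$time))
  tab <- table[keep, , drop = FALSE]
  if (!nrow(tab)) stop("empty-series error: no aggregate passes min_n", call. = FALSE)
  out <- lapply(properties, function(p) {
    ok <- is.finite(tab[[p]])
    m <- tapply(tab[[p]][ok], tab$time[ok], mean)
    property_timeseries(as.numeric(names(m)), as.numeric(m), name = p)
  })
  names(out) <- properties
  dropped <- setdiff(all_times, sort(unique(tab$time)))
  if (length(dropped)) {
    message(sprintf("reduce_aggregate_properties: %d frame(s) had no qualifying aggregate",
                    length(dropped)))
  }
  attr(out, "dropped_times") <- dropped
  out
}

#' Marginal-standard-error-rule truncation point
#'
#' Finds the truncation index `k*` minimizing
#' `MSE(k) = 1/(n-k)^2 * sum_{i=k}^{n-1} (Y_i - Ybar_{n,k})^2`
#' (0-based `i`; the sum runs over the last `n - k` points and
#' `Ybar_{n,k}` is their mean). The `(n-k)^-2` prefactor favors keeping data,
#' the sum penalizes deviation from the retained mean. `k` is scanned over
#' `0..k_max`; ties break toward the smallest `k`. An optional batch size
#' averages the series in non-overlapping blocks first.
#'
#' @param series A [property_timeseries()] or numeric vector.
#' @param k_max Largest truncation considered; default `floor(3n/4)`, which
#'   keeps the prefactor from degenerating as `k -> n`.
#' @param batch Optional batch (block-mean) size applied before the scan.
#' @return List: `k_star` (0-based truncation index), `mse` (length
#'   `k_max + 1`, `mse[k+1] = MSE(k)`), `k_max`, `batch`.
#' @export
mser_truncation <- function(series, k_max = NULL, batch = 1) {
  y <- if (inherits(series, "property_timeseries")) series$values else as.numeric(series)
  if (batch > 1) {
    nb <- floor(length(y) / batch)
    if (nb < 4) stop("too-short error: fewer than 4 batches", call. = FALSE)
    y <- as.numeric(tapply(y[seq_len(nb * batch)],
                           rep(seq_len(nb), each = batch), mean))
  }
  n <- length(y)
  if (n < 4) stop("too-short error: MSER needs at least 4 points", call. = FALSE)
  if (is.null(k_max)) k_max <- floor(3 * n / 4)
  k_max <- min(k_max, n - 2L)
  # suffix sums give every MSE(k) in one pass
  s1 <- rev(cumsum(rev(y)))        # s1[k+1] = sum_{i>=k} y_i (1-based storage)
  s2 <- rev(cumsum(rev(y^2)))
  k <- 0:k_max
  m <- n - k
  ss <- s2[k + 1] - s1[k + 1]^2 / m
  mse <- pmax(ss, 0) / m^2
  k_star <- k[which.min(mse)]
  list(k_star = k_star, mse = mse, k_max = k_max, batch = batch)
}

# MacKinnon (2010) response-surface critical values for the Dickey-Fuller
# tau distribution with a constant and no trend
.adf_critical_value <- function(n_obs, confidence) {
  tab <- list(
    "0.99" = c(-3.43035, -6.5393, -16.786, -79.433),
    "0.95" = c(-2.86154, -2.8903, -4.234, -40.040),
    "0.90" = c(-2.56677, -1.5384, -2.809, 0)
  )
  key <- sprintf("%.2f", confidence)
  if (is.null(tab[[key]])) {
    stop("confidence must be one of 0.90, 0.95, 0.99", call. = FALSE)
  }
  b <- tab[[key]]
  b[1] + b[2] / n_obs + b[3] / n_obs^2 + b[4] / n_obs^3
}

#' Augmented Dickey-Fuller stationarity check
#'
#' Tests the null hypothesis that the series has a unit root (is
#' nonstationary) with the regression
#' `dy_t = alpha + gamma * y_{t-1} + sum_j phi_j dy_{t-j} + e_t`
#' (constant, no trend). The lag order is selected by AIC over
#' `0..floor((n-1)^(1/3))`. The series is judged stationary when the test
#' statistic is below the critical value at the requested confidence.
#'
#' @param series A [property_timeseries()] or numeric vector (typically the
#'   MSER-truncated segment).
#' @param confidence One of 0.90, 0.95, 0.99 (default 0.99).
#' @param max_lag Maximum augmentation lag; default `floor((n-1)^(1/3))`.
#' @return List: `statistic`, `critical_value`, `stationary`, `lag`,
#'   `n_obs`, `degenerate` (constant input, treated as stationary with a
#'   warning).
#' @export
adf_stationarity <- function(series, confidence = 0.99, max_lag = NULL) {
  y <- if (inherits(series, "property_timeseries")) series$values else as.numeric(series)
  n <- length(y)
  if (n < 20) stop("ADF needs at least 20 observations", call. = FALSE)
  if (stats::sd(y) < .Machine$double.eps^0.5 * (abs(mean(y)) + 1)) {
    warning("zero-variance series: treated as stationary (degenerate)")
    return(list(statistic = -Inf, critical_value = NA_real_, stationary = TRUE,
                lag = 0L, n_obs = n, degenerate = TRUE))
  }
  if (is.null(max_lag)) max_lag <- floor((n - 1)^(1 / 3))
  dy <- diff(y)
  fit_lag <- function(p) {
    # common sample across candidate lags is not required here; each lag uses
    # its own longest sample, AIC compared on the shared (max_lag-trimmed) one
    nn <- length(dy)
    idx <- (max_lag + 1):nn
    X <- cbind(ylag = y[idx], 1)
    if (p > 0) {
      for (j in seq_len(p)) X <- cbind(X, dy[idx - j])
    }
    yy <- dy[idx]
    fit <- stats::lm.fit(X, yy)
    rss <- sum(fit$residuals^2)
    k <- ncol(X)
    nobs <- length(yy)
    aic <- nobs * log(rss / nobs) + 2 * k
    se <- sqrt(rss / (nobs - k) *
                 solve(crossprod(X))[1, 1])
    list(stat = fit$coefficients[1] / se, aic = aic, p = p, nobs = nobs)
  }
  fits <- lapply(0:max_lag, fit_lag)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]]
  cv <- .adf_critical_value(best$nobs, confidence)
  list(statistic = unname(best$stat), critical_value = cv,
       stationary = unname(best$stat) < cv, lag = best$p,
       n_obs = best$nobs, degenerate = FALSE)
}

#' Equilibration analysis of one property timeseries
#'
#' Combines MSER truncation with the augmented Dickey-Fuller stationarity
#' check: the series is truncated at the MSE-optimal index, the equilibrium
#' mean and standard deviation are computed over the retained segment, and
#' stationarity of that segment is verified.
#'
#' @param series A [property_timeseries()].
#' @param confidence ADF confidence level.
#' @param k_max,batch Passed to [mser_truncation()].
#' @return List with class `"equilibration_result"`: `name`, `k_star`,
#'   `t_star` (time at the truncation index), `mean`, `sd`, `mse`,
#'   `adf` (NULL when the retained segment is shorter than 20 points),
#'   `stationary`, `n`, `n_retained`.
#' @export
equilibrium_statistics <- function(series, confidence = 0.99, k_max = NULL,
                                   batch = 1) {
  stopifnot(inherits(series, "property_timeseries"))
  ms <- mser_truncation(series, k_max = k_max, batch = batch)
  y <- series$values
  n <- length(y)
  kept <- y[(ms$k_star + 1):n]
  adf <- if (length(kept) >= 20) {
    withCallingHandlers(
      adf_stationarity(kept, confidence = confidence),
      warning = function(w) invokeRestart("muffleWarning"))
  } else NULL
  structure(
    list(name = series$name, k_star = ms$k_star,
         t_star = series$times[ms$k_star + 1],
         mean = mean(kept), sd = stats::sd(kept), mse = ms$mse, adf = adf,
         stationary = if (is.null(adf)) NA else adf$stationary,
         n = n, n_retained = length(kept)),
    class = "equilibration_result"
  )
}

#' @export
print.equilibration_result <- function(x, ...) {
  cat(sprintf("<equilibration '%s': k*=%d (t=%.3g ns), mean=%.4g +/- %.3g, stationary=%s>\n",
              x$name, x$k_star, x$t_star, x$mean, x$sd,
              ifelse(is.na(x$stationary), "NA", x$stationary)))
  invisible(x)
}

#' Convergence report across properties
#'
#' Applies [equilibrium_statistics()] to each property series; the system
#' convergence time is the maximum truncation time across properties.
#'
#' @param series_list Named list of [property_timeseries()].
#' @param ... Passed to [equilibrium_statistics()].
#' @return List: `per_property` (list of equilibration results), `table`
#'   (data.frame summary), `final_convergence_time` (ns).
#' @export
convergence_report <- function(series_list, ...) {
  res <- lapply(series_list, equilibrium_statistics, ...)
  tab <- do.call(rbind, lapply(res, function(r) {
    data.frame(property = r$name, k_star = r$k_star, t_star = r$t_star,
               mean = r$mean, sd = r$sd,
               adf_statistic = if (is.null(r$adf)) NA_real_ else r$adf$statistic,
               stationary = r$stationary)
  }))
  rownames(tab) <- NULL
  list(per_property = res, table = tab,
       final_convergence_time = max(tab$t_star))
}

#' Binned timeseries means with bootstrap confidence intervals
#'
#' Means in fixed-width time bins with seeded percentile-bootstrap confidence
#' intervals of the bin mean. Empty bins are skipped with a message.
#'
#' @param series A [property_timeseries()].
#' @param bin_width Bin width in ns (default 100).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame: `bin_start`, `bin_mid`, `n`, `mean`, `ci_lo`, `ci_hi`.
#' @export
bin_timeseries <- function(series, bin_width = 100, n_boot = 1000,
                           conf = 0.95, seed = 1) {
  stopifnot(inherits(series, "property_timeseries"))
  t0 <- min(series$times)
  bin <- floor((series$times - t0) / bin_width)
  alpha <- (1 - conf) / 2
  withr::with_seed(seed, {
    rows <- lapply(sort(unique(bin)), function(b) {
      v <- series$values[bin == b]
      if (!length(v)) return(NULL)
      boot <- vapply(seq_len(n_boot),
                     function(i) mean(sample(v, length(v), replace = TRUE)),
                     numeric(1))
      ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
      data.frame(bin_start = t0 + b * bin_width,
                 bin_mid = t0 + (b + 0.5) * bin_width,
                 n = length(v), mean = mean(v), ci_lo = ci[1], ci_hi = ci[2])
    })
    do.call(rbind, rows)
  })
}
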