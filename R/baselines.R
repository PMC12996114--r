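#' Classical univariate baseline forecasters
#'
#' Reference forecasters applied independently to each KPI series of each
#' player. `moving_average_forecast()` predicts every future step as the mean
#' of the last `k` observations (a flat multi-step forecast).
#' `exponential_smoothing_forecast()` runs the simple exponential smoothing
#' level recursion \eqn{\ell_t = \alpha y_t + (1-\alpha)\ell_{t-1}} with
#' \eqn{\ell_1 = y_1} and forecasts flat at the final level.
#' `arima_forecast()` fits an ARIMA(p,d,q) by maximum likelihood
#' ([stats::arima()]) and forecasts recursively; `order = "auto"` selects the
#' order by AIC over the grid \eqn{p,q \le 2}, \eqn{d \le 1}.
#'
#' @param values Numeric vector, the observed series in time order.
#' @param k Moving-average window length, `1 <= k <= length(values)`.
#' @param alpha Smoothing weight in (0, 1].
#' @param order Integer vector `c(p, d, q)` or `"auto"`.
#' @param horizon Number of future steps to forecast.
#' @return Numeric vector of length `horizon`.
#' @examples
#' moving_average_forecast(c(1, 2, 3, 4), k = 2, horizon = 2)
#' exponential_smoothing_forecast(c(2, 4), alpha = 0.5, horizon = 3)
#' @export
moving_average_forecast <- function(values, k = 5, horizon = 1) {
  check_series(values)
  if (k < 1 || k > length(values)) {
    abort(paste0("k must be in [1, ", length(values), "], got ", k, "."),
          class = "workloadcast_parameter_error")
  }
  if (horizon < 1) abort("horizon must be >= 1.", class = "workloadcast_parameter_error")
  rep(mean(tail(values, k)), horizon)
}

#' @rdname moving_average_forecast
#' @export
exponential_smoothing_forecast <- function(values, alpha = 0.3, horizon = 1) {
  check_series(values)
  if (alpha <= 0 || alpha > 1) {
    abort("alpha must lie in (0, 1].", class = "workloadcast_parameter_error")
  }
  if (horizon < 1) abort("horizon must be >= 1.", class = "workloadcast_parameter_error")
  level <- values[1]
  for (y in values[-1]) level <- alpha * y + (1 - alpha) * level
  rep(level, horizon)
}

#' @rdname moving_average_forecast
#' @export
arima_forecast <- function(values, order = "auto", horizon = 1) {
  check_series(values)
  if (horizon < 1) abort("horizon must be >= 1.", class = "workloadcast_parameter_error")
  fit <- fit_arima(values, order)
  as.numeric(predict(fit, n.ahead = horizon)$pred)
}

fit_arima <- function(values, order) {
  if (identical(order, "auto")) {
    grid <- expand.grid(p = 0:2, d = 0:1, q = 0:2)
    best <- NULL; best_aic <- Inf
    for (i in seq_len(nrow(grid))) {
      o <- as.integer(grid[i, c("p", "d", "q")])
      if (length(values) < sum(o) + 2) next
      f <- try_arima(values, o)
      if (!is.null(f) && is.finite(f$aic) && f$aic < best_aic) {
        best <- f; best_aic <- f$aic
      }
    }
    if (is.null(best)) {
      abort("No ARIMA order in the search grid could be fitted.",
            class = "workloadcast_estimation_error")
    }
    return(best)
  }
  order <- as.integer(order)
  if (length(order) != 3 || any(order < 0)) {
    abort("order must be c(p, d, q) with non-negative entries, or \"auto\".",
          class = "workloadcast_parameter_error")
  }
  if (length(values) < sum(order) + 2) {
    abort(paste0("Series too short (", length(values), ") for ARIMA(",
                 paste(order, collapse = ","), ")."),
          class = "workloadcast_estimation_error")
  }
  f <- try_arima(values, order)
  if (is.null(f)) {
    warn("ARIMA fit failed or was non-invertible; falling back to AR(1).")
    f <- try_arima(values, c(1L, 0L, 0L))
    if (is.null(f)) {
      abort("Fallback AR(1) fit also failed.",
            class = "workloadcast_estimation_error")
    }
  }
  f
}

try_arima <- function(values, order) {
  tryCatch(
    suppressWarnings(stats::arima(values, order = order, method = "CSS-ML")),
    error = function(e) {
      tryCatch(suppressWarnings(stats::arima(values, order = order, method = "CSS")),
               error = function(e2) NULL)
    }
  )
}

check_series <- function(values) {
  if (!is.numeric(values) || length(values) < 1 || any(!is.finite(values))) {
    abort("The series must be a non-empty finite numeric vector.",
          class = "workloadcast_parameter_error")
  }
  invisible(values)
}

#' Forecast accuracy measures
#'
#' `rmse()` is the root mean squared error; `mape()` the mean absolute
#' percentage error, in percent. MAPE is undefined when an actual value is
#' (near) zero; an error is raised rather than clamping, since all six KPIs
#' are strictly positive in practice.
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return A single number (`mape()` in percent).
#' @examples
#' rmse(c(1, 3), c(2, 5)) # sqrt(2.5)
#' mape(c(100, 200), c(110, 180))
#' @export
rmse <- function(actual, predicted) {
  check_paired(actual, predicted)
  sqrt(mean((actual - predicted)^2))
}

#' @rdname rmse
#' @export
mape <- function(actual, predicted) {
  check_paired(actual, predicted)
  if (any(abs(actual) < 1e-8)) {
    abort(paste0("MAPE undefined: actual value near zero at position ",
                 which(abs(actual) < 1e-8)[1], "."),
          class = "workloadcast_parameter_error")
  }
  100 * mean(abs(actual - predicted) / abs(actual))
}

check_paired <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 1) {
    abort(paste0("actual (", length(actual), ") and predicted (",
                 length(predicted), ") must have equal positive length."),
          class = "workloadcast_parameter_error")
  }
  if (any(!is.finite(actual)) || any(!is.finite(predicted))) {
    abort("actual and predicted must be finite.",
          class = "workloadcast_parameter_error")
  }
  invisible(NULL)
}
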