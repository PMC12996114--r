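#' Chronological holdout split
#'
#' Withholds the last `horizon` sessions of every player as the test set; the
#' remainder is the history the models may see. Players with too few sessions
#' to leave any history are excluded with a warning (or an error).
#'
#' @param sessions A session panel.
#' @param horizon Number of trailing sessions per player to withhold.
#' @param incomplete `"warn_drop"` (default) or `"error"` for players with
#'   `<= horizon` sessions.
#' @return A list with `history` and `test` session tibbles; per player the
#'   largest history index is below the smallest test index.
#' @examples
#' sim <- simulate_sessions(sim_config(n_sessions = 30))
#' sp <- holdout_split(sim$sessions, horizon = 10)
#' @export
holdout_split <- function(sessions, horizon = 10,
                          incomplete = c("warn_drop", "error")) {
  incomplete <- match.arg(incomplete)
  panel <- validate_sessions(sessions)
  if (horizon < 1) abort("horizon must be >= 1.", class = "workloadcast_parameter_error")
  counts <- table(panel$player_id)
  bad <- names(counts)[counts <= horizon]
  if (length(bad) > 0) {
    if (incomplete == "error") {
      abort(paste0("Player(s) with <= horizon sessions: ",
                   paste(bad, collapse = ", ")),
            class = "workloadcast_validation_error")
    }
    warn(paste0("Excluding player(s) with <= ", horizon, " sessions: ",
                paste(bad, collapse = ", ")))
    panel <- panel[!panel$player_id %in% bad, ]
  }
  flagged <- panel %>%
    group_by(.data$player_id) %>%
    mutate(.test = row_number() > dplyr::n() - horizon) %>%
    ungroup()
  list(history = flagged %>% filter(!.data$.test) %>% select(-".test"),
       test = flagged %>% filter(.data$.test) %>% select(-".test"))
}

# ---- forecaster adapters ----------------------------------------------------

#' Forecaster adapters for model comparison
#'
#' Uniform wrappers used by [evaluate_models()]. Each adapter bundles a
#' `fit(history)` step (a no-op for the univariate baselines) and a
#' `forecast(state, history, player_id, horizon, future_types)` step that
#' returns a `horizon x 6` KPI matrix. The three classical baselines forecast
#' each KPI series independently and never see the session-type calendar —
#' exactly the information asymmetry the recurrent model exploits.
#'
#' @param k Moving-average window length.
#' @param alpha Exponential-smoothing weight in (0, 1].
#' @param order ARIMA order `c(p, d, q)` or `"auto"`.
#' @param config A [workload_config()] for the recurrent model.
#' @return An object of class `wl_forecaster`.
#' @export
forecaster_moving_average <- function(k = 5) {
  new_forecaster("moving_average", predict_uni = function(values, horizon) {
    moving_average_forecast(values, k = min(k, length(values)), horizon = horizon)
  })
}

#' @rdname forecaster_moving_average
#' @export
forecaster_exponential_smoothing <- function(alpha = 0.3) {
  new_forecaster("exponential_smoothing", predict_uni = function(values, horizon) {
    exponential_smoothing_forecast(values, alpha = alpha, horizon = horizon)
  })
}

#' @rdname forecaster_moving_average
#' @export
forecaster_arima <- function(order = "auto") {
  new_forecaster("arima", predict_uni = function(values, horizon) {
    arima_forecast(values, order = order, horizon = horizon)
  })
}

#' @rdname forecaster_moving_average
#' @export
forecaster_workload <- function(config = workload_config()) {
  structure(list(
    label = "lstm",
    fit = function(history) fit_workload(history, config),
    forecast = function(state, history, player_id, horizon, future_types) {
      fc <- forecast_workload(state, history, horizon = horizon,
                              players = player_id,
                              future_types = future_types)
      forecast_to_matrix(fc, horizon)
    },
    intervals = function(state, history, horizon, future_types, level, seed) {
      forecast_intervals(state, history, horizon = horizon,
                         future_types = future_types, level = level,
                         seed = seed)
    }
  ), class = "wl_forecaster")
}

new_forecaster <- function(label, predict_uni) {
  structure(list(
    label = label,
    fit = function(history) NULL,
    forecast = function(state, history, player_id, horizon, future_types) {
      sub <- history[history$player_id == player_id, ]
      sub <- sub[order(sub$session_index), ]
      m <- vapply(kpi_names(), function(kk) {
        predict_uni(sub[[kk]], horizon)
      }, numeric(horizon))
      matrix(m, nrow = horizon, dimnames = list(NULL, kpi_names()))
    },
    intervals = NULL
  ), class = "wl_forecaster")
}

forecast_to_matrix <- function(fc, horizon) {
  wide <- tidyr::pivot_wider(fc, names_from = "kpi", values_from = "estimate")
  as.matrix(wide[order(wide$step), kpi_names()])
}

#' Compare forecasters on a rolling holdout
#'
#' Withholds the last `horizon` sessions per player, fits every supplied
#' forecaster once on the pooled history, forecasts each player's test
#' horizon (the recurrent model receives the true future session types — the
#' calendar is known; baselines are univariate and ignore it), and pools the
#' residuals over all (player, step) pairs into one RMSE and MAPE per model
#' and KPI. For forecasters that expose intervals, empirical coverage of the
#' `level`-percent band over all (player, step, KPI) cells is also computed.
#'
#' @param sessions A session panel.
#' @param models Named list of [forecaster_moving_average()]-style adapters;
#'   names label the report rows.
#' @param horizon Test horizon per player.
#' @param level Interval level (percent) for coverage.
#' @param seed Seed forwarded to stochastic forecasters.
#' @return A `workload_eval` object: list with `metrics` (tibble: model, kpi,
#'   rmse, mape, n, n_missing), `coverage` (tibble: model, coverage), and the
#'   protocol settings. `tidy()` returns the metrics table.
#' @export
evaluate_models <- function(sessions, models, horizon = 10, level = 95,
                            seed = 1L) {
  if (length(models) < 1) {
    abort("At least one model is required.", class = "workloadcast_parameter_error")
  }
  if (is.null(names(models)) || any(names(models) == "")) {
    abort("`models` must be a fully named list.",
          class = "workloadcast_parameter_error")
  }
  sp <- holdout_split(sessions, horizon = horizon)
  history <- sp$history
  test <- sp$test
  players <- sort(unique(test$player_id))
  k <- kpi_names()

  cells <- list()
  coverage <- list()
  for (mn in names(models)) {
    mdl <- models[[mn]]
    state <- mdl$fit(history)
    for (pid in players) {
      fut <- test[test$player_id == pid, ]
      fut <- fut[order(fut$session_index), ]
      pred <- tryCatch(
        mdl$forecast(state, history, pid, horizon, fut$session_type),
        error = function(e) {
          warn(paste0("Model '", mn, "' failed on player '", pid, "': ",
                      conditionMessage(e)))
          matrix(NA_real_, horizon, 6, dimnames = list(NULL, k))
        })
      cells[[length(cells) + 1]] <- tibble(
        model = mn,
        player_id = pid,
        step = rep(seq_len(horizon), times = 6),
        kpi = rep(k, each = horizon),
        predicted = as.numeric(pred[, k]),
        actual = as.numeric(as.matrix(fut[k]))
      )
    }
    if (!is.null(mdl$intervals)) {
      fc <- mdl$intervals(state, history, horizon,
                          future_types = test[c("player_id", "session_type")] %>%
                            group_by(.data$player_id) %>%
                            mutate(step = row_number()) %>% ungroup(),
                          level = level, seed = derive_seed(seed, 42))
      coverage[[mn]] <- tibble(model = mn,
                               coverage = interval_coverage(fc, test))
    }
  }
  cell_tbl <- bind_rows(cells)
  metrics <- cell_tbl %>%
    group_by(.data$model, .data$kpi) %>%
    summarise(
      n = sum(is.finite(.data$predicted)),
      n_missing = sum(!is.finite(.data$predicted)),
      rmse = if (any(is.finite(.data$predicted)))
        rmse(.data$actual[is.finite(.data$predicted)],
             .data$predicted[is.finite(.data$predicted)]) else NA_real_,
      mape = if (any(is.finite(.data$predicted)))
        mape(.data$actual[is.finite(.data$predicted)],
             .data$predicted[is.finite(.data$predicted)]) else NA_real_,
      .groups = "drop"
    ) %>%
    mutate(model = factor(.data$model, levels = names(models)),
           kpi = factor(.data$kpi, levels = k)) %>%
    arrange(.data$model, .data$kpi) %>%
    mutate(model = as.character(.data$model), kpi = as.character(.data$kpi))
  structure(list(metrics = metrics, coverage = bind_rows(coverage),
                 cells = cell_tbl, horizon = horizon, level = level,
                 n_players = length(players), seed = seed),
            class = "workload_eval")
}

#' @export
print.workload_eval <- function(x, ...) {
  cat("Rolling holdout evaluation (horizon ", x$horizon, ", ",
      x$n_players, " players)\n\n", sep = "")
  print(tidyr::pivot_wider(x$metrics[c("model", "kpi", "rmse")],
                           names_from = "kpi", values_from = "rmse"))
  if (nrow(x$coverage) > 0) {
    cat("\nInterval coverage at ", x$level, "%:\n", sep = "")
    print(x$coverage)
  }
  invisible(x)
}

#' Relative improvement over the best baseline
#'
#' `100 * (best_baseline_rmse - model_rmse) / best_baseline_rmse`, reported
#' to one decimal: the headline percentage by which a model's error
#' undercuts the strongest classical baseline.
#'
#' @param model_rmse RMSE of the model of interest.
#' @param best_baseline_rmse Lowest baseline RMSE (must be positive).
#' @return Percent improvement, rounded to one decimal.
#' @examples
#' relative_improvement(1273.45, 1480.33)
#' @export
relative_improvement <- function(model_rmse, best_baseline_rmse) {
  if (any(best_baseline_rmse <= 0)) {
    abort("best_baseline_rmse must be positive.",
          class = "workloadcast_parameter_error")
  }
  round(100 * (best_baseline_rmse - model_rmse) / best_baseline_rmse, 1)
}

#' Empirical interval coverage
#'
#' Fraction (in percent) of test observations falling inside their forecast
#' interval, pooled over players, KPIs and horizon steps. Intervals are
#' closed: an actual on the boundary counts as covered.
#'
#' @param forecasts A `workload_forecast` tibble from [forecast_intervals()]
#'   (columns `player_id`, `step`, `kpi`, `lower`, `upper`).
#' @param actuals The test session panel; per player, its rows in session
#'   order correspond to steps 1, 2, ....
#' @return Coverage in percent.
#' @export
interval_coverage <- function(forecasts, actuals) {
  needed <- c("player_id", "step", "kpi", "lower", "upper")
  if (!all(needed %in% names(forecasts))) {
    abort("`forecasts` must have columns player_id/step/kpi/lower/upper.",
          class = "workloadcast_parameter_error")
  }
  test <- validate_sessions(actuals)
  long <- test %>%
    group_by(.data$player_id) %>%
    mutate(step = row_number()) %>%
    ungroup() %>%
    tidyr::pivot_longer(all_of(kpi_names()), names_to = "kpi",
                        values_to = "actual") %>%
    select("player_id", "step", "kpi", "actual")
  joined <- left_join(as_tibble(forecasts), long,
                      by = c("player_id", "step", "kpi"))
  if (any(is.na(joined$actual))) {
    miss <- joined[which(is.na(joined$actual))[1], ]
    abort(paste0("No actual value for (player '", miss$player_id, "', step ",
                 miss$step, ", kpi '", miss$kpi, "')."),
          class = "workloadcast_parameter_error")
  }
  100 * mean(joined$actual >= joined$lower & joined$actual <= joined$upper)
}
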