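test_that("holdout split is a clean per-player partition", {
  panel <- small_sim_panel(seed = 6, n_sessions = 30)$sessions
  sp <- holdout_split(panel, horizon = 10)
  for (pid in unique(panel$player_id)) {
    h <- sp$history[sp$history$player_id == pid, ]
    t <- sp$test[sp$test$player_id == pid, ]
    expect_equal(nrow(h), 20)
    expect_equal(nrow(t), 10)
    expect_lt(max(h$session_index), min(t$session_index))
    expect_setequal(c(h$session_index, t$session_index),
                    panel$session_index[panel$player_id == pid])
  }
  # boundary: horizon = n - 1 leaves a single history row
  one <- holdout_split(panel[panel$player_id == "wing_01", ], horizon = 29)
  expect_equal(nrow(one$history), 1)
  # players at or below the horizon are excluded with a warning, or error
  expect_warning(holdout_split(panel, horizon = 30), "wing_01")
  expect_error(holdout_split(panel, horizon = 30, incomplete = "error"),
               class = "workloadcast_validation_error")
})

test_that("a perfect oracle model scores zero RMSE on every KPI", {
  panel <- small_sim_panel(seed = 9, n_sessions = 25)$sessions
  oracle <- structure(list(
    label = "oracle",
    fit = function(history) holdout_split(panel, horizon = 5)$test,
    forecast = function(state, history, player_id, horizon, future_types) {
      fut <- state[state$player_id == player_id, ]
      as.matrix(fut[order(fut$session_index), kpi_names()])
    },
    intervals = NULL), class = "wl_forecaster")
  ev <- evaluate_models(panel, list(oracle = oracle), horizon = 5)
  expect_equal(nrow(ev$metrics), 6) # n_models x 6 KPIs
  expect_true(all(ev$metrics$rmse == 0))
  expect_true(all(ev$metrics$mape == 0))
})

test_that("pooled RMSE equals the direct formula on concatenated residuals", {
  panel <- small_sim_panel(seed = 10, n_sessions = 25)$sessions
  ev <- evaluate_models(panel,
                        list(ma = forecaster_moving_average(3)), horizon = 4)
  expect_equal(nrow(ev$metrics), 6)
  sp <- holdout_split(panel, horizon = 4)
  # brute force for one KPI: per player, flat mean-of-last-3 forecast
  acts <- c(); preds <- c()
  for (pid in unique(panel$player_id)) {
    h <- sp$history[sp$history$player_id == pid, ]
    t <- sp$test[sp$test$player_id == pid, ]
    acts <- c(acts, t$speed_max)
    preds <- c(preds, rep(mean(tail(h$speed_max, 3)), 4))
  }
  expect_equal(ev$metrics$rmse[ev$metrics$kpi == "speed_max"],
               rmse(acts, preds))
  expect_equal(ev$metrics$mape[ev$metrics$kpi == "speed_max"],
               mape(acts, preds))
})

test_that("corrupting test values never changes a model's forecasts", {
  panel <- small_sim_panel(seed = 14, n_sessions = 25)$sessions
  sp <- holdout_split(panel, horizon = 5)
  corrupted <- panel
  sel <- corrupted$session_index >= 20
  corrupted[sel, kpi_names()] <- corrupted[sel, kpi_names()] * 10
  for (mk in list(forecaster_moving_average(5),
                  forecaster_exponential_smoothing(0.4))) {
    for (pid in c("wing_01", "back_02")) {
      f1 <- mk$forecast(NULL, holdout_split(panel, horizon = 5)$history,
                        pid, 5, rep("training", 5))
      f2 <- mk$forecast(NULL, holdout_split(corrupted, horizon = 5)$history,
                        pid, 5, rep("training", 5))
      expect_identical(f1, f2)
    }
  }
})

test_that("a failing model is recorded per cell, not dropped", {
  panel <- small_sim_panel(seed = 15, n_sessions = 25)$sessions
  flaky <- structure(list(
    label = "flaky",
    fit = function(history) NULL,
    forecast = function(state, history, player_id, horizon, future_types) {
      if (player_id == "wing_01") stop("boom")
      matrix(1000, horizon, 6, dimnames = list(NULL, kpi_names()))
    },
    intervals = NULL), class = "wl_forecaster")
  expect_warning(ev <- evaluate_models(panel, list(flaky = flaky), horizon = 3),
                 "wing_01")
  expect_true(all(ev$metrics$n_missing == 3))
  expect_true(all(is.finite(ev$metrics$rmse)))
})

test_that("model comparison report covers models x KPIs with labels", {
  panel <- small_sim_panel(seed = 16, n_sessions = 20)$sessions
  ev <- evaluate_models(panel,
                        list(ma = forecaster_moving_average(5),
                             ses = forecaster_exponential_smoothing(0.3)),
                        horizon = 3)
  expect_equal(nrow(ev$metrics), 2 * 6)
  expect_equal(unique(ev$metrics$model), c("ma", "ses"))
  g <- glance(ev)
  expect_equal(g$n_models, 2)
  expect_equal(g$horizon, 3)
  expect_s3_class(tidy(ev), "tbl_df")
})
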