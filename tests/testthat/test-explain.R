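test_that("linear-map attribution equals the absolute weights exactly", {
  set.seed(4)
  W <- matrix(rnorm(3 * 7 * 6), 3 * 7, 6)
  lf <- linear_forecaster(W)
  for (kpi in c("distance_total", "jumps")) {
    im <- gradient_importance(lf, target_kpi = kpi)
    k_idx <- match(kpi, kpi_names())
    expected <- abs(matrix(W[, k_idx], nrow = 3, byrow = TRUE))
    got <- matrix(im$score, nrow = 3)
    expect_equal(got, expected, tolerance = 1e-6)
  }
  # constant (zero-weight) model attributes nothing
  im0 <- gradient_importance(linear_forecaster(matrix(0, 21, 6)))
  expect_true(all(im0$score == 0))
})

test_that("analytic input gradients agree with finite differences", {
  panel <- small_sim_panel(seed = 19, n_sessions = 30)$sessions
  fit <- fit_workload(panel, small_config(max_epochs = 6, seed = 8))
  im <- gradient_importance(fit, panel, "wing_01",
                            target_kpi = "distance_total")
  L <- fit$config$window_length
  state <- workloadcast:::window_state(fit, validate_sessions(panel), "wing_01")
  f_of <- function(x_arr) {
    workloadcast:::nn_forward(fit$model$params, fit$config, x_arr, 0,
                              state$player,
                              channel_mask = fit$model$channel_mask,
                              exo_mask = fit$model$exo_mask)$y[1, 1]
  }
  eps <- 1e-4
  fd <- matrix(0, L, 7)
  for (t in seq_len(L)) {
    for (ch in 1:7) {
      xp <- state$x; xm <- state$x
      xp[1, t, ch] <- xp[1, t, ch] + eps
      xm[1, t, ch] <- xm[1, t, ch] - eps
      fd[t, ch] <- (f_of(xp) - f_of(xm)) / (2 * eps)
    }
  }
  analytic <- matrix(im$score, nrow = L)
  expect_lt(max(abs(analytic - abs(fd))) / max(abs(analytic)), 1e-3)
})

test_that("a structurally disconnected channel has exactly zero importance", {
  panel <- small_sim_panel(seed = 20, n_sessions = 30)$sessions
  fit <- fit_workload(panel, small_config(max_epochs = 4, seed = 9,
                                          use_exogenous = FALSE))
  im <- gradient_importance(fit, panel, "wing_01")
  exo_scores <- im$score[im$channel == "session_type"]
  expect_true(all(exo_scores == 0))
  expect_true(any(im$score[im$channel != "session_type"] > 0))
})

test_that("later-horizon attributions are well-formed and deterministic", {
  panel <- small_sim_panel(seed = 22, n_sessions = 30)$sessions
  fit <- fit_workload(panel, small_config(max_epochs = 4, seed = 10))
  im2a <- gradient_importance(fit, panel, "back_01", horizon_step = 2)
  im2b <- gradient_importance(fit, panel, "back_01", horizon_step = 2)
  expect_identical(im2a, im2b)
  expect_equal(nrow(im2a), fit$config$window_length * 7)
  expect_true(all(im2a$score >= 0))
  expect_equal(attr(im2a, "horizon_step"), 2)
})

test_that("aggregation conserves total score and projects one-hot maps", {
  set.seed(6)
  scores <- matrix(abs(rnorm(4 * 7)), 4, 7,
                   dimnames = list(NULL, workloadcast:::importance_channels()))
  im <- workloadcast:::new_importance_map(scores, "distance_total", 1L)
  by_ch <- aggregate_importance(im, by = "channel")
  by_lag <- aggregate_importance(im, by = "lag")
  expect_equal(sum(by_ch$score), sum(scores))
  expect_equal(sum(by_lag$score), sum(scores))
  # brute-force axis sums
  expect_equal(by_ch$score,
               unname(colSums(scores)[workloadcast:::importance_channels()]))
  expect_equal(by_lag$score, unname(rowSums(scores)))
  # one-hot map: aggregation is a coordinate projection
  oh <- matrix(0, 4, 7,
               dimnames = list(NULL, workloadcast:::importance_channels()))
  oh[2, 3] <- 5
  im_oh <- workloadcast:::new_importance_map(oh, "speed_max", 1L)
  ch <- aggregate_importance(im_oh, by = "channel")
  expect_equal(ch$score[ch$channel == "metabolic_power_max"], 5)
  expect_equal(sum(ch$score), 5)
  # sum-to-one renormalisation
  nm <- aggregate_importance(im, by = "channel", normalization = "sum_to_one")
  expect_equal(sum(nm$score), 1, tolerance = 1e-9)
})

test_that("the template renderer is deterministic with canonical tie-breaks", {
  # equal weights across all channels: top-3 must follow canonical order
  W <- matrix(1, 2 * 7, 6)
  im <- gradient_importance(linear_forecaster(W), target_kpi = "distance_total")
  fc <- fake_forecast("p01", horizon = 3, mean_val = 90)
  panel <- constant_panel(n_players = 1, n_sessions = 8)
  r1 <- render_report(fc, im, panel, "p01")
  r2 <- render_report(fc, im, panel, "p01")
  expect_identical(r1, r2)
  expect_match(r1, "distance_total, speed_max, metabolic_power_max")

  # top channel distance + forecast below recent mean -> fatigue flag
  # (panel distance level is 6000, forecast mean 90)
  expect_match(r1, "possible\\s+accumulated fatigue")

  # empty attribution -> explicit no-attribution text
  im0 <- gradient_importance(linear_forecaster(matrix(0, 14, 6)))
  r0 <- render_report(fc, im0, panel, "p01")
  expect_match(r0, "No attribution available")
})
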