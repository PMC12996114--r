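test_that("default configuration carries the published position profiles", {
  cfg <- sim_config()
  expect_equal(cfg$position_means["wing", "distance_total"], 5294.5)
  expect_equal(cfg$position_means["pivot", "speed_max"], 22.4)
  expect_equal(cfg$position_means["back", "metabolic_power_max"], 8173.6)
  expect_equal(cfg$n_sessions, 108L)
  expect_equal(sum(cfg$n_players_per_position), 15)
  expect_silent(workloadcast:::validate_sim_config(cfg))
  # correlation matrix is a valid PSD correlation matrix
  ev <- eigen(cfg$kpi_correlation, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(match_probability = 1.2),
               class = "workloadcast_config_error")
  expect_error(sim_config(ar_coefficient = 1),
               class = "workloadcast_config_error")
  bad_r <- default_kpi_correlation(); bad_r[1, 2] <- 0.9 # asymmetric
  expect_error(sim_config(kpi_correlation = bad_r),
               class = "workloadcast_config_error")
})

test_that("degenerate noiseless training panel is exactly the position mean", {
  cfg <- sim_config(noise_cv = 0, ar_coefficient = 0, state_sd_frac = 0,
                    player_sd_frac = 0, match_probability = 0,
                    n_sessions = 6, seed = 3)
  panel <- simulate_sessions(cfg)$sessions
  wings <- panel[panel$position == "wing", ]
  expect_true(all(wings$distance_total == 5294.5))
  expect_true(all(wings$speed_max == 26.1))
  pivots <- panel[panel$position == "pivot", ]
  expect_true(all(pivots$changes_of_direction == 22.9))
})

test_that("simulation is deterministic in the seed and always non-negative", {
  a <- simulate_sessions(sim_config(n_sessions = 12, seed = 9))
  b <- simulate_sessions(sim_config(n_sessions = 12, seed = 9))
  expect_identical(a$sessions, b$sessions)
  c <- simulate_sessions(sim_config(n_sessions = 12, seed = 10))
  expect_false(identical(a$sessions, c$sessions))
  for (k in kpi_names()) expect_true(all(a$sessions[[k]] >= 0))
})

test_that("match sessions raise distance when the multiplier exceeds one", {
  panel <- simulate_sessions(sim_config(n_sessions = 400, seed = 21))$sessions
  m <- tapply(panel$distance_total, panel$session_type, mean)
  expect_gt(m["match"], m["training"])
})

test_that("noiseless panels give exact recovery of means and multipliers", {
  cfg <- sim_config(noise_cv = 0, ar_coefficient = 0, state_sd_frac = 0,
                    player_sd_frac = 0, match_probability = 0.4,
                    n_sessions = 20, seed = 4)
  rec <- recover_parameters(simulate_sessions(cfg)$sessions)
  wing_row <- rec$position_means[rec$position_means$position == "wing", ]
  expect_equal(wing_row$distance_total, 5294.5, tolerance = 1e-10)
  expect_equal(unname(rec$match_multiplier["distance_total"]), 1.15,
               tolerance = 1e-10)
  expect_equal(unname(rec$match_multiplier["jumps"]), 1.0, tolerance = 1e-10)
})

test_that("a zero-AR panel shows no residual lag-1 autocorrelation", {
  cfg <- sim_config(ar_coefficient = 0, n_sessions = 400, seed = 8)
  rec <- recover_parameters(simulate_sessions(cfg)$sessions)
  # ~ 15 players x 400 sessions x 6 KPIs of pooled lag pairs
  expect_lt(abs(rec$lag1_autocorrelation), 0.03)
})

test_that("recovery names a missing session type or lop-sided position", {
  cfg <- sim_config(match_probability = 0, n_sessions = 10, seed = 2)
  expect_error(recover_parameters(simulate_sessions(cfg)$sessions),
               class = "workloadcast_estimation_error")
})
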