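test_that("model construction satisfies its structural contracts", {
  cfg <- small_config(seed = 5)
  m <- build_workload_model(cfg, players = c("a", "b", "c"))
  # embedding table: one row per player, embedding_dim columns
  expect_equal(dim(m$params$emb), c(3, cfg$embedding_dim))
  # output head emits all six KPIs simultaneously
  expect_equal(ncol(m$params$out$W), 6)
  # same seed, same initial parameters; different seed differs
  m2 <- build_workload_model(cfg, players = c("a", "b", "c"))
  expect_identical(m$params, m2$params)
  m3 <- build_workload_model(small_config(seed = 6), players = c("a", "b", "c"))
  expect_false(identical(m$params, m3$params))
  expect_error(build_workload_model(cfg, players = character(0)),
               class = "workloadcast_config_error")
  expect_error(workload_config(dropout_rate = 1),
               class = "workloadcast_config_error")
})

test_that("forward pass output dimension is six for any batch", {
  cfg <- small_config()
  m <- build_workload_model(cfg, players = c("a", "b"))
  x <- array(rnorm(4 * cfg$window_length * 7), c(4, cfg$window_length, 7))
  y <- workloadcast:::nn_forward(m$params, cfg, x, exo_next = rep(0, 4),
                                 player = c(1, 2, 1, 2))$y
  expect_equal(dim(y), c(4, 6))
  expect_true(all(is.finite(y)))
})

test_that("backpropagation matches central finite differences", {
  cfg <- workload_config(window_length = 4, lstm_units = 5, lstm_layers = 2,
                         embedding_dim = 3, dense_widths = c(6, 4),
                         dropout_rate = 0, seed = 2)
  m <- build_workload_model(cfg, players = c("a", "b"))
  set.seed(3)
  x <- array(rnorm(2 * 4 * 7), c(2, 4, 7))
  exo <- c(1, 0); pl <- c(1, 2)
  target <- matrix(rnorm(12), 2, 6)
  loss_of <- function(params) {
    y <- workloadcast:::nn_forward(params, cfg, x, exo, pl,
                                   channel_mask = m$channel_mask,
                                   exo_mask = m$exo_mask)$y
    sum((y - target)^2)
  }
  fwd <- workloadcast:::nn_forward(m$params, cfg, x, exo, pl,
                                   channel_mask = m$channel_mask,
                                   exo_mask = m$exo_mask, keep_cache = TRUE)
  grads <- workloadcast:::nn_backward(m$params, cfg, fwd$cache,
                                      2 * (fwd$y - target))
  eps <- 1e-5
  # a spread of parameters across every component
  check <- list(
    list(path = c("lstm", 1, "Wx"), idx = c(3, 7)),
    list(path = c("lstm", 2, "Wh"), idx = c(2, 11)),
    list(path = c("lstm", 1, "b"), idx = 6),
    list(path = c("emb"), idx = c(2, 1)),
    list(path = c("dense", 1, "W"), idx = c(4, 2)),
    list(path = c("out", "W"), idx = c(1, 5))
  )
  for (cc in check) {
    get_set <- function(params, delta) {
      p <- params
      ref <- p
      # navigate
      if (cc$path[1] == "emb") {
        p$emb[matrix(cc$idx, 1)] <- p$emb[matrix(cc$idx, 1)] + delta
      } else if (length(cc$path) == 3) {
        i1 <- as.integer(cc$path[2])
        slot <- cc$path[3]
        if (length(cc$idx) == 2) {
          p[[cc$path[1]]][[i1]][[slot]][matrix(cc$idx, 1)] <-
            p[[cc$path[1]]][[i1]][[slot]][matrix(cc$idx, 1)] + delta
        } else {
          p[[cc$path[1]]][[i1]][[slot]][cc$idx] <-
            p[[cc$path[1]]][[i1]][[slot]][cc$idx] + delta
        }
      } else {
        p[[cc$path[1]]][[cc$path[2]]][matrix(cc$idx, 1)] <-
          p[[cc$path[1]]][[cc$path[2]]][matrix(cc$idx, 1)] + delta
      }
      p
    }
    fd <- (loss_of(get_set(m$params, eps)) -
             loss_of(get_set(m$params, -eps))) / (2 * eps)
    g <- if (cc$path[1] == "emb") {
      grads$emb[matrix(cc$idx, 1)]
    } else if (length(cc$path) == 3) {
      gm <- grads[[cc$path[1]]][[as.integer(cc$path[2])]][[cc$path[3]]]
      if (length(cc$idx) == 2) gm[matrix(cc$idx, 1)] else gm[cc$idx]
    } else {
      grads[[cc$path[1]]][[cc$path[2]]][matrix(cc$idx, 1)]
    }
    expect_equal(g, fd, tolerance = 1e-5)
  }
})

test_that("training memorises a constant-per-player panel", {
  panel <- constant_panel(n_players = 3, n_sessions = 25)
  cfg <- workload_config(window_length = 4, lstm_units = 8, embedding_dim = 3,
                         dense_widths = 8, dropout_rate = 0,
                         learning_rate = 5e-3, batch_size = 32,
                         max_epochs = 50, patience = 50, seed = 1)
  fit <- fit_workload(panel, cfg)
  h <- tidy(fit)
  expect_lt(h$train_loss[nrow(h)], 0.01) # normalised MSE ~ 0
})

test_that("fitting is deterministic given the seed", {
  panel <- small_sim_panel(seed = 12, n_sessions = 25)$sessions
  cfg <- small_config(max_epochs = 5, seed = 7)
  f1 <- fit_workload(panel, cfg)
  f2 <- fit_workload(panel, cfg)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$model$params, f2$model$params)
})

test_that("players with too little history are dropped or rejected", {
  panel <- small_sim_panel(seed = 12, n_sessions = 25)$sessions
  short <- dplyr::filter(panel, !(player_id == "wing_01" & session_index > 2))
  cfg <- small_config(max_epochs = 2)
  expect_warning(fit_workload(short, cfg), "wing_01")
  expect_error(fit_workload(short, cfg, too_short = "error"),
               class = "workloadcast_validation_error")
})

test_that("recursive forecasts obey the prefix property and physical bounds", {
  panel <- small_sim_panel(seed = 13, n_sessions = 30)$sessions
  fit <- fit_workload(panel, small_config(max_epochs = 8, seed = 2))
  f1 <- forecast_workload(fit, panel, horizon = 1)
  f10 <- forecast_workload(fit, panel, horizon = 10)
  expect_equal(dplyr::filter(f10, step == 1), f1)
  expect_true(all(is.finite(f10$estimate)))
  expect_true(all(f10$estimate >= 0))
  expect_error(forecast_workload(fit, panel, players = "nobody"),
               class = "workloadcast_parameter_error")
})

test_that("on noiseless data forecasts recover mean times match effect", {
  sim <- simulate_sessions(sim_config(
    n_players_per_position = c(wing = 2, back = 2, pivot = 2),
    n_sessions = 60, noise_cv = 0, ar_coefficient = 0, state_sd_frac = 0,
    player_sd_frac = 0, match_probability = 0.3, seed = 31))
  cfg <- workload_config(window_length = 6, lstm_units = 12,
                         embedding_dim = 3, dense_widths = 16,
                         dropout_rate = 0, learning_rate = 5e-3,
                         batch_size = 64, max_epochs = 60, patience = 60,
                         seed = 4)
  fit <- fit_workload(sim$sessions, cfg)
  fc_m <- forecast_workload(fit, sim$sessions, players = "wing_01",
                            horizon = 1, future_types = "match")
  fc_t <- forecast_workload(fit, sim$sessions, players = "wing_01",
                            horizon = 1, future_types = "training")
  d_m <- fc_m$estimate[fc_m$kpi == "distance_total"]
  d_t <- fc_t$estimate[fc_t$kpi == "distance_total"]
  expect_equal(d_t, 5294.5, tolerance = 0.05)
  expect_equal(d_m, 5294.5 * 1.15, tolerance = 0.05)
  expect_gt(d_m, d_t)
})
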