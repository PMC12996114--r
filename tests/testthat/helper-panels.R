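# Small programmatic fixtures shared across the test files.

# A hand-sized panel with known values: two wings, one back, values chosen so
# per-position means are easy to compute by hand.
tiny_panel <- function() {
  base <- tibble::tibble(
    player_id = c("w1", "w1", "w2", "b1"),
    session_index = c(0L, 1L, 0L, 0L),
    session_type = c("training", "match", "training", "training"),
    position = c("wing", "wing", "wing", "back"),
    distance_total = c(5000, 6000, 5200, 4400),
    speed_max = c(25, 27, 26, 24),
    metabolic_power_max = c(5500, 5800, 5600, 8100),
    accel_load_accum = c(600, 650, 610, 540),
    jumps = c(17, 20, 18, 14),
    changes_of_direction = c(55, 60, 56, 35)
  )
  base
}

# Panel where every player's series is constant (distinct levels per player):
# a model with an embedding must be able to memorise it.
constant_panel <- function(n_players = 3, n_sessions = 20) {
  purrr::map_dfr(seq_len(n_players), function(j) {
    lev <- 1 + 0.5 * j
    tibble::tibble(
      player_id = sprintf("p%02d", j),
      session_index = seq_len(n_sessions) - 1L,
      session_type = "training",
      position = c("wing", "back", "pivot")[(j - 1) %% 3 + 1],
      distance_total = 4000 * lev, speed_max = 20 * lev,
      metabolic_power_max = 5000 * lev, accel_load_accum = 500 * lev,
      jumps = 10 * lev, changes_of_direction = 30 * lev
    )
  })
}

# Quick deterministic simulated panel at reduced scale for model tests.
small_sim_panel <- function(seed = 11, n_sessions = 40,
                            players = c(wing = 2, back = 2, pivot = 1), ...) {
  simulate_sessions(sim_config(n_players_per_position = players,
                               n_sessions = n_sessions, seed = seed, ...))
}

# A small, quickly trainable model configuration; `...` overrides defaults.
small_config <- function(...) {
  args <- utils::modifyList(
    list(window_length = 5, lstm_units = 8, embedding_dim = 2,
         dense_widths = 8, batch_size = 64, max_epochs = 15, patience = 5),
    list(...))
  do.call(workload_config, args)
}

# Hand-built interval-forecast object (for renderer / coverage tests).
fake_forecast <- function(players, horizon, kpis = kpi_names(),
                          mean_val = 100, width = 10, level = 95) {
  df <- tidyr::expand_grid(player_id = players, step = seq_len(horizon),
                           kpi = kpis)
  df$mean <- mean_val
  df$lower <- mean_val - width / 2
  df$upper <- mean_val + width / 2
  structure(df, level = level, n_mc_samples = 2, horizon = horizon,
            class = c("workload_forecast", class(df)))
}
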