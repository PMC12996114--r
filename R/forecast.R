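# ---- recursive rollout ------------------------------------------------------

# Assemble the latest input window (normalised) for a set of players.
window_state <- function(fit, panel, players) {
  L <- fit$config$window_length
  k <- kpi_names()
  B <- length(players)
  x <- array(0, dim = c(B, L, 7))
  for (j in seq_len(B)) {
    sub <- panel[panel$player_id == players[j], ]
    if (nrow(sub) < L) {
      abort(paste0("Player '", players[j], "' has fewer than window_length (",
                   L, ") sessions of history."),
            class = "workloadcast_validation_error")
    }
    tail_rows <- tail(sub[order(sub$session_index), ], L)
    x[j, , 1:6] <- scale_kpis(as.matrix(tail_rows[k]), fit$norm)
    x[j, , 7] <- as.numeric(tail_rows$session_type == "match")
  }
  list(x = x, player = match(players, fit$players))
}

# Normalise the future session-type specification into a B x H 0/1 matrix.
future_type_matrix <- function(future_types, players, horizon) {
  if (is.null(future_types)) future_types <- "training"
  if (is.data.frame(future_types)) {
    m <- matrix(NA_real_, length(players), horizon)
    for (i in seq_len(nrow(future_types))) {
      j <- match(future_types$player_id[i], players)
      s <- future_types$step[i]
      if (!is.na(j) && s >= 1 && s <= horizon) {
        m[j, s] <- as.numeric(future_types$session_type[i] == "match")
      }
    }
    if (any(is.na(m))) {
      abort("future_types data frame does not cover every (player, step).",
            class = "workloadcast_parameter_error")
    }
    return(m)
  }
  ft <- as.character(future_types)
  if (!all(ft %in% session_types())) {
    abort("future_types must be 'training'/'match' values.",
          class = "workloadcast_parameter_error")
  }
  if (length(ft) == 1) ft <- rep(ft, horizon)
  if (length(ft) != horizon) {
    abort("future_types must have length 1 or `horizon`.",
          class = "workloadcast_parameter_error")
  }
  matrix(rep(as.numeric(ft == "match"), each = length(players)),
         length(players), horizon)
}

# Recursive multi-step rollout on the normalised scale. Each predicted step
# is fed back as the newest window row together with its known session type.
# Returns a B x H x 6 array of normalised predictions.
rollout_norm <- function(fit, state, ft_mat, masks = NULL) {
  cfg <- fit$config
  L <- cfg$window_length
  B <- dim(state$x)[1]
  horizon <- ncol(ft_mat)
  x <- state$x
  out <- array(0, dim = c(B, horizon, 6))
  for (s in seq_len(horizon)) {
    y <- nn_forward(fit$model$params, cfg, x, ft_mat[, s], state$player,
                    masks = masks, channel_mask = fit$model$channel_mask,
                    exo_mask = fit$model$exo_mask)$y
    out[, s, ] <- y
    if (L > 1) x[, 1:(L - 1), ] <- x[, 2:L, , drop = FALSE]
    x[, L, 1:6] <- y
    x[, L, 7] <- ft_mat[, s]
  }
  out
}

# Single-player convenience used by residual calibration: physical-scale
# point predictions (dropout off), matrix horizon x 6.
rollout_point <- function(fit, hist_rows, future_types) {
  pid <- hist_rows$player_id[1]
  state <- window_state(fit, hist_rows, pid)
  ft <- future_type_matrix(future_types, pid, length(future_types))
  nrm <- rollout_norm(fit, state, ft)
  pred <- unscale_kpis(matrix(nrm[1, , ], ncol = 6), fit$norm)
  colnames(pred) <- kpi_names()
  pmax(pred, 0)
}

#' Point forecasts from a fitted workload model
#'
#' Recursive multi-step forecasts: each predicted session is fed back as
#' input for the next step, with the session type of every future step
#' supplied from the (known) team calendar. Dropout is disabled; outputs are
#' de-normalised to physical units and clamped at zero.
#'
#' @param object A `workload_fit` from [fit_workload()].
#' @param sessions Session panel providing each player's history (at least
#'   `window_length` sessions per player).
#' @param horizon Number of future sessions to forecast.
#' @param players Player ids to forecast; default all players seen in
#'   training.
#' @param future_types Future session types: a single value, a length-
#'   `horizon` vector shared by all players, or a data frame with columns
#'   `player_id`, `step`, `session_type`.
#' @return A tibble with columns `player_id`, `step`, `kpi`, `estimate`.
#' @export
forecast_workload <- function(object, sessions, horizon = 10, players = NULL,
                              future_types = "training") {
  stopifnot(inherits(object, "workload_fit"))
  if (horizon < 1) abort("horizon must be >= 1.", class = "workloadcast_parameter_error")
  panel <- validate_sessions(sessions)
  players <- resolve_players(object, panel, players)
  state <- window_state(object, panel, players)
  ft <- future_type_matrix(future_types, players, horizon)
  nrm <- rollout_norm(object, state, ft)
  tidy_forecast_array(nrm, object, players, horizon, point_only = TRUE)
}

#' MC-dropout prediction intervals
#'
#' Runs `n_mc` stochastic forward rollouts with dropout active (one
#' variational mask set per pass, held fixed across the recursive steps of
#' that pass). The point estimate is the MC sample mean; the interval at
#' `level` percent is the Gaussian band
#' \eqn{\bar y \pm z \sqrt{\sigma^2_{epi} + \sigma^2_{alea}}}, where the
#' epistemic variance is the across-pass sample variance and the aleatoric
#' variance is the per-KPI, per-step residual variance estimated at training
#' time (MC spread alone reflects only parameter uncertainty and would
#' under-cover observed sessions). All three of lower/mean/upper are clamped
#' at zero after de-normalisation, preserving their order.
#'
#' @inheritParams forecast_workload
#' @param level Interval level in percent, in (0, 100).
#' @param n_mc Number of MC-dropout passes (>= 2); default from the config.
#' @param seed Seed for the dropout draws; default derived from the fit seed,
#'   so repeated calls are identical.
#' @return A `workload_forecast` tibble: `player_id`, `step`, `kpi`, `mean`,
#'   `lower`, `upper`, with attributes `level`, `n_mc_samples`, `horizon`.
#' @export
forecast_intervals <- function(object, sessions, horizon = 10, players = NULL,
                               future_types = "training", level = 95,
                               n_mc = NULL, seed = NULL) {
  stopifnot(inherits(object, "workload_fit"))
  if (level <= 0 || level >= 100) {
    abort("level must lie in (0, 100).", class = "workloadcast_parameter_error")
  }
  if (is.null(n_mc)) n_mc <- object$config$n_mc_samples
  if (n_mc < 2) abort("n_mc must be >= 2.", class = "workloadcast_parameter_error")
  if (horizon < 1) abort("horizon must be >= 1.", class = "workloadcast_parameter_error")
  panel <- validate_sessions(sessions)
  players <- resolve_players(object, panel, players)
  state <- window_state(object, panel, players)
  ft <- future_type_matrix(future_types, players, horizon)
  cfg <- object$config
  B <- length(players)
  if (is.null(seed)) seed <- derive_seed(cfg$seed, 303)
  set.seed(seed)
  sum1 <- array(0, dim = c(B, horizon, 6))
  sum2 <- array(0, dim = c(B, horizon, 6))
  for (s in seq_len(n_mc)) {
    masks <- nn_masks(B, cfg$lstm_units, cfg$lstm_layers, cfg$dense_widths,
                      cfg$dropout_rate)
    nrm <- rollout_norm(object, state, ft, masks = masks)
    sum1 <- sum1 + nrm
    sum2 <- sum2 + nrm^2
  }
  mc_mean <- sum1 / n_mc
  mc_var <- pmax(sum2 / n_mc - mc_mean^2, 0) * n_mc / max(n_mc - 1, 1)

  rv <- object$residual_var$step_var
  alea <- rv[pmin(seq_len(horizon), nrow(rv)), , drop = FALSE]
  z <- qnorm(1 - (1 - level / 100) / 2)
  tot_sd <- sqrt(sweep(mc_var, c(2, 3), alea, "+"))
  lower <- mc_mean - z * tot_sd
  upper <- mc_mean + z * tot_sd
  out <- tidy_forecast_array(mc_mean, object, players, horizon,
                             lower = lower, upper = upper)
  structure(out, level = level, n_mc_samples = n_mc, horizon = horizon,
            class = c("workload_forecast", class(out)))
}

resolve_players <- function(object, panel, players) {
  if (is.null(players)) {
    players <- intersect(object$players, unique(panel$player_id))
  }
  unknown <- setdiff(players, object$players)
  if (length(unknown) > 0) {
    abort(paste0("Unknown player_id(s): ", paste(unknown, collapse = ", ")),
          class = "workloadcast_parameter_error")
  }
  missing_hist <- setdiff(players, unique(panel$player_id))
  if (length(missing_hist) > 0) {
    abort(paste0("No history in `sessions` for: ",
                 paste(missing_hist, collapse = ", ")),
          class = "workloadcast_parameter_error")
  }
  players
}

tidy_forecast_array <- function(nrm, fit, players, horizon, lower = NULL,
                                upper = NULL, point_only = FALSE) {
  k <- kpi_names()
  B <- length(players)
  # rows of matrix(a, ncol = 6) are ordered step-major (player fastest);
  # reorder to player-major, then flatten KPI-fastest
  row_order <- as.vector(t(matrix(seq_len(B * horizon), B, horizon)))
  flat <- function(a) {
    m <- pmax(unscale_kpis(matrix(a, ncol = 6), fit$norm), 0)
    as.numeric(t(m[row_order, , drop = FALSE]))
  }
  out <- tibble(player_id = rep(players, each = horizon * 6),
                step = rep(rep(seq_len(horizon), each = 6), times = B),
                kpi = rep(k, times = B * horizon))
  if (point_only) {
    out$estimate <- flat(nrm)
  } else {
    out$mean <- flat(nrm)
    out$lower <- flat(lower)
    out$upper <- flat(upper)
  }
  out
}
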