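#' Gradient-based feature importance
#'
#' Sensitivity of a predicted KPI to every cell of the input window:
#' `score(lag, channel) = |d prediction / d input(lag, channel)|`, evaluated
#' with dropout disabled. For the recurrent forecaster the gradient at
#' horizon step 1 is exact (backpropagation through time to the inputs); for
#' later horizon steps — where the prediction is a recursive composition
#' through fed-back forecasts — central finite differences on the rollout are
#' used. `measure = "gradient_x_input"` weights each gradient by the input
#' value instead of taking the raw magnitude.
#'
#' @param object A fitted model: a `workload_fit` or a [linear_forecaster()].
#' @param ... Method arguments.
#' @return An `importance_map`: tibble with columns `lag` (1 = oldest row of
#'   the window), `channel` (six KPI names plus `"session_type"`), `score`,
#'   and attributes `target_kpi`, `horizon_step`, `aggregation`,
#'   `normalization`.
#' @export
gradient_importance <- function(object, ...) UseMethod("gradient_importance")

importance_channels <- function() c(kpi_names(), "session_type")

new_importance_map <- function(scores, target_kpi, horizon_step,
                               aggregation = "per_cell",
                               normalization = "none") {
  L <- nrow(scores)
  out <- tibble(lag = rep(seq_len(L), times = ncol(scores)),
                channel = rep(colnames(scores), each = L),
                score = as.numeric(scores))
  structure(out, target_kpi = target_kpi, horizon_step = horizon_step,
            aggregation = aggregation, normalization = normalization,
            class = c("importance_map", class(out)))
}

#' @rdname gradient_importance
#' @param sessions Session panel supplying the player's latest window.
#' @param player_id Player to explain.
#' @param target_kpi KPI whose prediction is attributed.
#' @param horizon_step Forecast step being attributed (default 1).
#' @param future_types Future session types for the rollout (as in
#'   [forecast_workload()]).
#' @param measure `"gradient"` (absolute gradient, default) or
#'   `"gradient_x_input"`.
#' @export
gradient_importance.workload_fit <- function(object, sessions, player_id,
                                             target_kpi = "distance_total",
                                             horizon_step = 1,
                                             future_types = "training",
                                             measure = c("gradient",
                                                         "gradient_x_input"),
                                             ...) {
  measure <- match.arg(measure)
  if (!target_kpi %in% kpi_names()) {
    abort(paste0("Unknown target_kpi: ", target_kpi),
          class = "workloadcast_parameter_error")
  }
  if (horizon_step < 1) {
    abort("horizon_step must be >= 1.", class = "workloadcast_parameter_error")
  }
  panel <- validate_sessions(sessions)
  players <- resolve_players(object, panel, player_id)
  state <- window_state(object, panel, players)
  ft <- future_type_matrix(future_types, players, max(horizon_step, 1))
  k_idx <- match(target_kpi, kpi_names())
  cfg <- object$config
  L <- cfg$window_length

  if (horizon_step == 1) {
    fwd <- nn_forward(object$model$params, cfg, state$x, ft[, 1],
                      state$player, channel_mask = object$model$channel_mask,
                      exo_mask = object$model$exo_mask, keep_cache = TRUE)
    dY <- matrix(0, 1, 6)
    dY[1, k_idx] <- 1
    grads <- nn_backward(object$model$params, cfg, fwd$cache, dY)
    g <- matrix(grads$dx[1, , ], nrow = L)
  } else {
    # prediction at step s is a recursive function of the original window;
    # differentiate the composed rollout numerically
    f_of <- function(x_arr) {
      st <- list(x = x_arr, player = state$player)
      nrm <- rollout_norm(object, st, ft)
      nrm[1, horizon_step, k_idx]
    }
    eps <- 1e-4
    g <- matrix(0, L, 7)
    for (t in seq_len(L)) {
      for (ch in 1:7) {
        xp <- state$x; xm <- state$x
        xp[1, t, ch] <- xp[1, t, ch] + eps
        xm[1, t, ch] <- xm[1, t, ch] - eps
        g[t, ch] <- (f_of(xp) - f_of(xm)) / (2 * eps)
      }
    }
  }
  if (measure == "gradient_x_input") {
    g <- g * matrix(state$x[1, , ], nrow = L)
  }
  scores <- abs(g)
  colnames(scores) <- importance_channels()
  new_importance_map(scores, target_kpi, horizon_step)
}

#' A bare linear map, for attribution oracles
#'
#' A minimal differentiable model `y = x W` mapping a flattened input window
#' to the six KPI outputs, whose attribution is known in closed form (the
#' absolute weights). Used to validate the gradient machinery.
#'
#' @param weights A `(window_length * 7) x 6` matrix; rows ordered lag-major
#'   (lag 1 channels first).
#' @param window_length Window length implied by `weights`.
#' @return An object of class `linear_forecaster`.
#' @export
linear_forecaster <- function(weights, window_length = nrow(weights) / 7) {
  if (nrow(weights) != window_length * 7 || ncol(weights) != 6) {
    abort("weights must be (window_length * 7) x 6.",
          class = "workloadcast_parameter_error")
  }
  structure(list(weights = weights, window_length = as.integer(window_length)),
            class = "linear_forecaster")
}

#' @rdname gradient_importance
#' @export
gradient_importance.linear_forecaster <- function(object,
                                                  target_kpi = "distance_total",
                                                  ...) {
  k_idx <- match(target_kpi, kpi_names())
  if (is.na(k_idx)) {
    abort(paste0("Unknown target_kpi: ", target_kpi),
          class = "workloadcast_parameter_error")
  }
  w <- object$weights[, k_idx]
  scores <- abs(matrix(w, nrow = object$window_length, ncol = 7, byrow = TRUE))
  colnames(scores) <- importance_channels()
  new_importance_map(scores, target_kpi, 1L)
}

#' Aggregate an importance map
#'
#' Collapses the per-cell scores by summing over lags (giving one score per
#' input channel) or over channels (one score per lag); the total score is
#' conserved. Optionally renormalises the result to sum to one.
#'
#' @param map An `importance_map`.
#' @param by `"channel"` or `"lag"`.
#' @param normalization `"none"` or `"sum_to_one"`.
#' @return A reduced `importance_map` tibble (`channel` or `lag` plus
#'   `score`).
#' @export
aggregate_importance <- function(map, by = c("channel", "lag"),
                                 normalization = c("none", "sum_to_one")) {
  by <- match.arg(by)
  normalization <- match.arg(normalization)
  stopifnot(inherits(map, "importance_map"))
  key <- if (by == "channel") "channel" else "lag"
  out <- as_tibble(map) %>%
    group_by(.data[[key]]) %>%
    summarise(score = sum(.data$score), .groups = "drop")
  if (by == "channel") {
    out <- out %>%
      mutate(channel = factor(.data$channel, levels = importance_channels())) %>%
      arrange(.data$channel) %>%
      mutate(channel = as.character(.data$channel))
  } else {
    out <- arrange(out, .data$lag)
  }
  if (normalization == "sum_to_one" && sum(out$score) > 0) {
    out$score <- out$score / sum(out$score)
  }
  structure(out, target_kpi = attr(map, "target_kpi"),
            horizon_step = attr(map, "horizon_step"),
            aggregation = paste0("per_", by), normalization = normalization,
            class = c("importance_map", class(tibble())))
}
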