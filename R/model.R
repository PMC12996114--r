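#' Forecaster configuration
#'
#' Hyperparameters of the multi-target recurrent workload forecaster. The
#' model consumes, for each prediction, a window of `window_length` past
#' sessions (six z-normalised KPI channels plus a binary session-type
#' channel), the session type of the step being predicted (the calendar is
#' known ahead), and a learned per-player embedding; an LSTM stack summarises
#' the window, the summary is concatenated with the embedding and the
#' next-step type flag, and a fully connected head emits all six KPIs at
#' once. Dropout (variational, rate `dropout_rate`) acts on the recurrent
#' state, the final hidden state and every dense hidden layer; the same
#' dropout machinery provides Monte-Carlo uncertainty at inference.
#'
#' Defaults are sized for desk-scale squads: window 10 sessions, 32 LSTM
#' units in one layer, 4-dimensional player embedding, one 32-unit dense
#' hidden layer, dropout 0.2, Adam with learning rate 1e-3, batch 128, at
#' most 60 epochs with early stopping (patience 8) on a per-player
#' chronological validation split.
#'
#' @param window_length Number of lagged sessions per input window.
#' @param lstm_units Hidden units per LSTM layer.
#' @param lstm_layers Number of stacked LSTM layers.
#' @param embedding_dim Dimension of the player embedding.
#' @param dense_widths Integer vector of dense hidden-layer widths.
#' @param dropout_rate Dropout probability in `[0, 1)`.
#' @param learning_rate,batch_size,max_epochs,patience Optimiser settings.
#' @param val_fraction Fraction (per player, chronological tail) of provided
#'   history reserved for validation/early stopping.
#' @param n_mc_samples Default number of MC-dropout forward passes.
#' @param use_exogenous If `FALSE`, the session-type channel is structurally
#'   disconnected (ablation).
#' @param seed Integer seed controlling initialisation, shuffling and dropout.
#' @return An object of class `workload_config`.
#' @export
workload_config <- function(window_length = 10, lstm_units = 32,
                            lstm_layers = 1, embedding_dim = 4,
                            dense_widths = 32, dropout_rate = 0.2,
                            learning_rate = 1e-3, batch_size = 128,
                            max_epochs = 60, patience = 8,
                            val_fraction = 0.15, n_mc_samples = 100,
                            use_exogenous = TRUE, seed = 1L) {
  cfg <- structure(list(
    window_length = as.integer(window_length),
    lstm_units = as.integer(lstm_units),
    lstm_layers = as.integer(lstm_layers),
    embedding_dim = as.integer(embedding_dim),
    dense_widths = as.integer(dense_widths),
    dropout_rate = dropout_rate,
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    patience = as.integer(patience),
    val_fraction = val_fraction,
    n_mc_samples = as.integer(n_mc_samples),
    use_exogenous = isTRUE(use_exogenous),
    seed = as.integer(seed)
  ), class = "workload_config")
  validate_workload_config(cfg)
  cfg
}

validate_workload_config <- function(cfg) {
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    abort("dropout_rate must lie in [0, 1).", class = "workloadcast_config_error")
  }
  sizes <- c(cfg$window_length, cfg$lstm_units, cfg$lstm_layers,
             cfg$embedding_dim, cfg$dense_widths, cfg$batch_size,
             cfg$max_epochs, cfg$n_mc_samples)
  if (any(sizes < 1)) {
    abort("All size hyperparameters must be >= 1.",
          class = "workloadcast_config_error")
  }
  if (cfg$val_fraction <= 0 || cfg$val_fraction >= 1) {
    abort("val_fraction must lie in (0, 1).", class = "workloadcast_config_error")
  }
  invisible(cfg)
}

#' Build an untrained workload model
#'
#' Instantiates the network for a given player roster with seeded parameter
#' initialisation. Mostly useful for inspection and tests; [fit_workload()]
#' builds and trains in one call.
#'
#' @param config A [workload_config()].
#' @param players Character vector of player ids (rows of the embedding table).
#' @return An object of class `workload_model` with the parameter list, the
#'   player index, and the structural channel masks.
#' @export
build_workload_model <- function(config = workload_config(), players) {
  validate_workload_config(config)
  players <- as.character(players)
  if (length(players) < 1) {
    abort("At least one player is required.", class = "workloadcast_config_error")
  }
  set.seed(derive_seed(config$seed, 101))
  params <- nn_init(n_channels = 7, units = config$lstm_units,
                    n_layers = config$lstm_layers,
                    emb_dim = config$embedding_dim,
                    dense_widths = config$dense_widths,
                    n_players = length(players))
  channel_mask <- c(rep(1, 6), as.numeric(config$use_exogenous))
  structure(list(config = config, players = players, params = params,
                 channel_mask = channel_mask,
                 exo_mask = as.numeric(config$use_exogenous)),
            class = "workload_model")
}

# ---- window construction ----------------------------------------------------

# Builds supervised windows from a panel: for every player and every target
# position t (1-based row position within the player's ordered history) with
# t > window_length, the input is rows (t-L)..(t-1) and the target is row t.
# Values are z-normalised with `norm` (list of mean/sd per KPI).
build_windows <- function(panel, window_length, norm, players) {
  k <- kpi_names()
  xs <- list(); ys <- list(); exo <- list(); pl <- list()
  pid <- list(); pos_in_series <- list()
  for (j in seq_along(players)) {
    sub <- panel[panel$player_id == players[j], ]
    n <- nrow(sub)
    if (n < window_length + 1) next
    km <- scale_kpis(as.matrix(sub[k]), norm)
    ex <- as.numeric(sub$session_type == "match")
    n_t <- n - window_length
    xarr <- array(0, dim = c(n_t, window_length, 7))
    for (t in seq_len(n_t)) {
      idx <- t:(t + window_length - 1)
      xarr[t, , 1:6] <- km[idx, ]
      xarr[t, , 7] <- ex[idx]
    }
    xs[[length(xs) + 1]] <- xarr
    ys[[length(ys) + 1]] <- km[(window_length + 1):n, , drop = FALSE]
    exo[[length(exo) + 1]] <- ex[(window_length + 1):n]
    pl[[length(pl) + 1]] <- rep(j, n_t)
    pid[[length(pid) + 1]] <- rep(players[j], n_t)
    pos_in_series[[length(pos_in_series) + 1]] <- (window_length + 1):n
  }
  if (length(xs) == 0) {
    return(list(n = 0))
  }
  n_tot <- sum(vapply(xs, function(a) dim(a)[1], integer(1)))
  x <- array(0, dim = c(n_tot, window_length, 7))
  ofs <- 0
  for (a in xs) {
    nr <- dim(a)[1]
    x[(ofs + 1):(ofs + nr), , ] <- a
    ofs <- ofs + nr
  }
  list(n = n_tot, x = x, y = do.call(rbind, ys), exo_next = unlist(exo),
       player = unlist(pl), player_id = unlist(pid),
       target_pos = unlist(pos_in_series))
}

scale_kpis <- function(m, norm) {
  sweep(sweep(m, 2, norm$mean, "-"), 2, norm$sd, "/")
}

unscale_kpis <- function(m, norm) {
  sweep(sweep(m, 2, norm$sd, "*"), 2, norm$mean, "+")
}

subset_windows <- function(w, idx) {
  list(n = length(idx), x = w$x[idx, , , drop = FALSE],
       y = w$y[idx, , drop = FALSE], exo_next = w$exo_next[idx],
       player = w$player[idx], player_id = w$player_id[idx],
       target_pos = w$target_pos[idx])
}

#' Fit the workload forecaster
#'
#' Trains the multi-target recurrent model on a session panel. Per player,
#' the chronological tail (`val_fraction` of their sessions, at least 3) is
#' held out for validation/early stopping; per-KPI z-normalisation statistics
#' are computed from the training sessions only. Optimisation is Adam on the
#' mean squared error over all six normalised targets, with minibatch
#' shuffling, dropout regularisation and early stopping on validation loss
#' (best-epoch weights are restored). After training, one-step residual
#' variances and rolling-origin multi-step residual variances (per KPI and
#' horizon step, on the normalised scale) are estimated from the validation
#' tail; these supply the aleatoric component of the MC-dropout prediction
#' intervals.
#'
#' The whole procedure is deterministic given `config$seed` and the data.
#'
#' @param sessions A session panel; every player must contribute at least
#'   `window_length + 2` sessions (offenders are dropped with a warning, or
#'   raise an error when `too_short = "error"`).
#' @param config A [workload_config()].
#' @param too_short `"warn_drop"` or `"error"` for players with insufficient
#'   history.
#' @param quiet Suppress per-epoch progress.
#' @return An object of class `workload_fit`: the trained model plus
#'   normalisation statistics, the per-epoch loss report, and residual
#'   variance estimates. Use [forecast_workload()], [forecast_intervals()],
#'   [gradient_importance()], [tidy()]/[glance()]/[autoplot()] on it.
#' @export
fit_workload <- function(sessions, config = workload_config(),
                         too_short = c("warn_drop", "error"), quiet = TRUE) {
  too_short <- match.arg(too_short)
  panel <- validate_sessions(sessions)
  validate_workload_config(config)
  L <- config$window_length
  counts <- table(panel$player_id)
  bad <- names(counts)[counts < L + 2]
  if (length(bad) > 0) {
    if (too_short == "error") {
      abort(paste0("Player(s) with fewer than window_length + 2 sessions: ",
                   paste(bad, collapse = ", ")),
            class = "workloadcast_validation_error")
    }
    warn(paste0("Dropping player(s) with too little history: ",
                paste(bad, collapse = ", ")))
    panel <- panel[!panel$player_id %in% bad, ]
  }
  players <- sort(unique(panel$player_id))
  if (length(players) == 0) {
    abort("No player has enough history to train on.",
          class = "workloadcast_validation_error")
  }

  # per-player chronological train/validation split over target positions
  n_val <- function(n) max(3L, ceiling(config$val_fraction * n))
  train_rows <- panel %>%
    group_by(.data$player_id) %>%
    mutate(.is_val = row_number() > dplyr::n() - n_val(dplyr::n())) %>%
    ungroup()
  norm_src <- as.matrix(train_rows[!train_rows$.is_val, kpi_names()])
  norm <- list(mean = colMeans(norm_src),
               sd = pmax(apply(norm_src, 2, sd), 1e-8))
  val_cut <- train_rows %>%
    group_by(.data$player_id) %>%
    summarise(n_total = dplyr::n(), n_val = n_val(dplyr::n()), .groups = "drop")

  w <- build_windows(panel, L, norm, players)
  is_val <- rep(FALSE, w$n)
  for (i in seq_len(nrow(val_cut))) {
    sel <- w$player_id == val_cut$player_id[i] &
      w$target_pos > val_cut$n_total[i] - val_cut$n_val[i]
    is_val <- is_val | sel
  }
  wtr <- subset_windows(w, which(!is_val))
  wva <- subset_windows(w, which(is_val))
  if (wtr$n == 0 || wva$n == 0) {
    abort("Not enough windows to form a train/validation split.",
          class = "workloadcast_validation_error")
  }

  model <- build_workload_model(config, players)
  params <- model$params
  opt <- adam_init(params)
  set.seed(derive_seed(config$seed, 202))

  mse_of <- function(p, ws) {
    pred <- nn_forward(p, config, ws$x, ws$exo_next, ws$player,
                       channel_mask = model$channel_mask,
                       exo_mask = model$exo_mask)$y
    mean((pred - ws$y)^2)
  }

  history <- tibble(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  best_val <- Inf; best_params <- params; best_epoch <- 0L; stall <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(wtr$n)
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    ep_loss <- 0
    for (b in batches) {
      wb <- subset_windows(wtr, b)
      masks <- nn_masks(wb$n, config$lstm_units, config$lstm_layers,
                        config$dense_widths, config$dropout_rate)
      fwd <- nn_forward(params, config, wb$x, wb$exo_next, wb$player,
                        masks = masks, channel_mask = model$channel_mask,
                        exo_mask = model$exo_mask, keep_cache = TRUE)
      err <- fwd$y - wb$y
      ep_loss <- ep_loss + sum(err^2)
      dY <- 2 * err / (wb$n * ncol(wb$y))
      grads <- nn_backward(params, config, fwd$cache, dY)
      stepped <- adam_step(params, grads, opt, config$learning_rate)
      params <- stepped$params
      opt <- stepped$state
    }
    tr_loss <- ep_loss / (wtr$n * 6)
    va_loss <- mse_of(params, wva)
    history <- bind_rows(history, tibble(epoch = epoch, train_loss = tr_loss,
                                         val_loss = va_loss))
    if (!quiet) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, tr_loss, va_loss))
    }
    if (va_loss < best_val - 1e-7) {
      best_val <- va_loss; best_params <- params
      best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  model$params <- best_params

  fit <- structure(list(
    model = model, config = config, players = players, norm = norm,
    report = list(history = history, selected_epoch = best_epoch,
                  best_val_loss = best_val, seed = config$seed,
                  n_train_windows = wtr$n, n_val_windows = wva$n),
    residual_var = NULL
  ), class = "workload_fit")

  fit$residual_var <- estimate_residual_variance(fit, panel, horizon = 10)
  fit
}

# One-step and rolling-origin multi-step residual variances on the normalised
# scale, pooled over players; used as the aleatoric interval component.
# Origins are placed so the forecast targets fall in each player's validation
# tail (data the selected weights were not fitted on).
estimate_residual_variance <- function(fit, panel, horizon = 10) {
  cfg <- fit$config
  k <- kpi_names()
  L <- cfg$window_length
  res <- vector("list", 0)
  for (pid in fit$players) {
    sub <- panel[panel$player_id == pid, ]
    n <- nrow(sub)
    for (origin in unique(pmax(c(n - horizon, n - horizon - 4), L))) {
      h_avail <- min(horizon, n - origin)
      if (h_avail < 1 || origin < L) next
      hist_rows <- sub[1:origin, ]
      fut <- sub[(origin + 1):(origin + h_avail), ]
      pred <- rollout_point(fit, hist_rows, future_types = fut$session_type)
      actual <- scale_kpis(as.matrix(fut[k]), fit$norm)
      predn <- scale_kpis(pred, fit$norm)
      for (h in seq_len(h_avail)) {
        res[[length(res) + 1]] <- tibble(step = h,
                                         kpi = k,
                                         e2 = as.numeric((predn[h, ] - actual[h, ])^2))
      }
    }
  }
  if (length(res) == 0) {
    return(list(step_var = matrix(1, horizon, 6, dimnames = list(NULL, k)),
                horizon = horizon))
  }
  tab <- bind_rows(res) %>%
    group_by(.data$step, .data$kpi) %>%
    summarise(v = mean(.data$e2), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "kpi", values_from = "v")
  sv <- matrix(NA_real_, horizon, 6, dimnames = list(NULL, k))
  for (i in seq_len(nrow(tab))) sv[tab$step[i], k] <- as.numeric(tab[i, k])
  # fill gaps forward, then smooth over steps (variance estimates from ~15-30
  # squared residuals per cell are noisy)
  for (h in seq_len(horizon)) {
    if (any(is.na(sv[h, ]))) sv[h, ] <- if (h == 1) 1 else sv[h - 1, ]
  }
  sm <- sv
  for (h in seq_len(horizon)) {
    lo <- max(1, h - 1); hi <- min(horizon, h + 1)
    sm[h, ] <- colMeans(sv[lo:hi, , drop = FALSE])
  }
  list(step_var = sm, horizon = horizon)
}
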