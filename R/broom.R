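#' Broom-style accessors for fitted objects
#'
#' `tidy()` on a `workload_fit` returns the per-epoch loss history;
#' `glance()` a one-row model summary. On a `workload_eval`, `tidy()` returns
#' the per-model, per-KPI accuracy table and `glance()` the protocol summary.
#'
#' @param x A `workload_fit` or `workload_eval`.
#' @param ... Ignored.
#' @return A tibble.
#' @name workload-tidiers
NULL

#' @rdname workload-tidiers
#' @method tidy workload_fit
#' @export
tidy.workload_fit <- function(x, ...) {
  x$report$history
}

#' @rdname workload-tidiers
#' @method glance workload_fit
#' @export
glance.workload_fit <- function(x, ...) {
  n_par <- function(p) {
    if (is.list(p)) sum(vapply(p, n_par, numeric(1))) else length(p)
  }
  tibble(selected_epoch = x$report$selected_epoch,
         best_val_loss = x$report$best_val_loss,
         n_parameters = n_par(x$model$params),
         n_players = length(x$players),
         n_train_windows = x$report$n_train_windows,
         n_val_windows = x$report$n_val_windows,
         seed = x$config$seed)
}

#' @rdname workload-tidiers
#' @method tidy workload_eval
#' @export
tidy.workload_eval <- function(x, ...) {
  x$metrics
}

#' @rdname workload-tidiers
#' @method glance workload_eval
#' @export
glance.workload_eval <- function(x, ...) {
  tibble(n_models = length(unique(x$metrics$model)),
         n_players = x$n_players, horizon = x$horizon, level = x$level,
         seed = x$seed)
}

#' @export
print.workload_fit <- function(x, ...) {
  g <- glance(x)
  cat("Multi-target recurrent workload forecaster\n")
  cat("  players:", g$n_players, " parameters:", g$n_parameters, "\n")
  cat("  selected epoch:", g$selected_epoch,
      " validation MSE:", signif(g$best_val_loss, 4), "\n")
  invisible(x)
}
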