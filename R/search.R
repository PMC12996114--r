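#' Random hyperparameter search
#'
#' Samples up to `budget` configurations uniformly from a grid (a named list
#' of candidate values for [workload_config()] arguments), trains each on the
#' panel, and returns the configuration with the lowest validation loss
#' together with the full trial log.
#'
#' @param sessions A session panel.
#' @param space Named list of candidate values, e.g.
#'   `list(lstm_units = c(16, 32), dropout_rate = c(0.1, 0.2))`.
#' @param budget Maximum number of configurations to train.
#' @param base_config Settings shared by all trials.
#' @param seed Seed controlling which configurations are sampled; trial
#'   `i` trains with seed `seed + i`.
#' @return A list with `best_config` (a `workload_config`), `best_fit`, and
#'   `trials` (tibble of sampled values and validation losses).
#' @export
tune_workload <- function(sessions, space, budget = 4,
                          base_config = workload_config(), seed = 1L) {
  if (!is.list(space) || length(space) == 0 || is.null(names(space))) {
    abort("`space` must be a non-empty named list of candidate values.",
          class = "workloadcast_parameter_error")
  }
  if (budget < 1) abort("budget must be >= 1.", class = "workloadcast_parameter_error")
  bad <- setdiff(names(space), names(unclass(base_config)))
  if (length(bad) > 0) {
    abort(paste0("Unknown config field(s) in space: ", paste(bad, collapse = ", ")),
          class = "workloadcast_parameter_error")
  }
  set.seed(derive_seed(seed, 404))
  trials <- list()
  best <- NULL
  for (i in seq_len(budget)) {
    draw <- lapply(space, function(v) {
      if (is.list(v)) v[[sample.int(length(v), 1)]] else v[sample.int(length(v), 1)]
    })
    cfg_args <- modifyList(unclass(base_config), draw)
    cfg_args$seed <- derive_seed(seed, 500 + i)
    cfg <- do.call(workload_config, cfg_args)
    fit <- fit_workload(sessions, cfg)
    loss <- fit$report$best_val_loss
    trials[[i]] <- tibble(trial = i, val_loss = loss,
                          !!!lapply(draw, function(x) if (length(x) == 1) x else list(x)))
    if (is.null(best) || loss < best$loss) {
      best <- list(config = cfg, fit = fit, loss = loss)
    }
  }
  list(best_config = best$config, best_fit = best$fit,
       trials = bind_rows(trials))
}
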