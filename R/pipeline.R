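#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_pipeline()]: the simulator (or a
#' CSV to ingest instead), the forecaster, the baselines, and the evaluation
#' protocol. The global `seed` re-seeds every sub-configuration so one
#' integer reproduces the whole run.
#'
#' @param sim A [sim_config()]; ignored when `input_csv` is given.
#' @param model A [workload_config()].
#' @param input_csv Optional path to a session CSV to use instead of
#'   simulating.
#' @param moving_average_k,ses_alpha,arima_order Baseline settings.
#' @param horizon Test horizon per player.
#' @param level Interval level in percent.
#' @param explain_kpi KPI attributed in the per-player reports.
#' @param seed Global seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), model = workload_config(),
                            input_csv = NULL, moving_average_k = 5,
                            ses_alpha = 0.3, arima_order = "auto",
                            horizon = 10, level = 95,
                            explain_kpi = "distance_total", seed = 1L) {
  if (horizon < 1 || level <= 0 || level >= 100) {
    abort("horizon must be >= 1 and level in (0, 100).",
          class = "workloadcast_config_error")
  }
  sim$seed <- derive_seed(seed, 1)
  model$seed <- derive_seed(seed, 2)
  structure(list(sim = sim, model = model, input_csv = input_csv,
                 moving_average_k = moving_average_k, ses_alpha = ses_alpha,
                 arima_order = arima_order, horizon = as.integer(horizon),
                 level = level, explain_kpi = explain_kpi,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full monitoring pipeline
#'
#' Simulate (or ingest) a session panel, hold out the last `horizon` sessions
#' per player, fit the recurrent forecaster and the three classical
#' baselines, evaluate them, produce MC-dropout interval forecasts, per-player
#' attributions and text reports, and write every artifact plus a manifest to
#' `out_dir`. Re-running with the same configuration reproduces all outputs.
#'
#' Artifacts written: `sessions.csv`, `ground_truth.json` (simulated runs),
#' `evaluation.csv`, `forecasts.csv`, `importance.csv`, `report.md`,
#' `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory results (`sessions`, `fit`,
#'   `evaluation`, `forecasts`, `importance`, `reports`, `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run_"),
                         quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("stage: data")
  truth <- NULL
  if (!is.null(config$input_csv)) {
    sessions <- read_sessions(config$input_csv)
  } else {
    sim <- simulate_sessions(config$sim)
    sessions <- sim$sessions
    truth <- sim$truth
  }
  write_sessions(sessions, file.path(out_dir, "sessions.csv"))
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(config = serializable_sim_config(truth$config),
           calendar = truth$calendar),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  say("stage: evaluate")
  models <- list(
    moving_average = forecaster_moving_average(config$moving_average_k),
    arima = forecaster_arima(config$arima_order),
    exponential_smoothing = forecaster_exponential_smoothing(config$ses_alpha),
    lstm = forecaster_workload(config$model)
  )
  ev <- evaluate_models(sessions, models, horizon = config$horizon,
                        level = config$level, seed = config$seed)
  readr::write_csv(ev$metrics, file.path(out_dir, "evaluation.csv"))

  say("stage: forecast")
  sp <- holdout_split(sessions, horizon = config$horizon)
  fit <- fit_workload(sp$history, config$model)
  fc <- forecast_intervals(fit, sp$history, horizon = config$horizon,
                           level = config$level)
  readr::write_csv(as_tibble(fc), file.path(out_dir, "forecasts.csv"))

  say("stage: explain")
  players <- sort(unique(sp$history$player_id))
  imps <- list(); reports <- character(0)
  for (pid in players) {
    im <- gradient_importance(fit, sp$history, pid,
                              target_kpi = config$explain_kpi)
    imps[[pid]] <- as_tibble(im) %>% mutate(player_id = pid, .before = 1)
    reports[pid] <- render_report(fc, im, sp$history, pid,
                                  target_kpi = config$explain_kpi)
  }
  readr::write_csv(bind_rows(imps), file.path(out_dir, "importance.csv"))

  best_baseline <- ev$metrics %>%
    filter(.data$model != "lstm", .data$kpi == "distance_total") %>%
    summarise(r = min(.data$rmse)) %>% pull("r")
  lstm_rmse <- ev$metrics %>%
    filter(.data$model == "lstm", .data$kpi == "distance_total") %>%
    pull("rmse")
  md <- c(
    "# Workload monitoring run", "",
    paste0("Players: ", length(players), "; horizon: ", config$horizon,
           "; interval level: ", config$level, "%"), "",
    "## Model comparison (RMSE)", "",
    knit_table(tidyr::pivot_wider(ev$metrics[c("model", "kpi", "rmse")],
                                  names_from = "kpi", values_from = "rmse")),
    "",
    sprintf("Relative improvement of the recurrent model over the best baseline (distance_total): %.1f%%",
            relative_improvement(lstm_rmse, best_baseline)),
    "", "## Player reports", "",
    unlist(lapply(players, function(p) c(paste0("### ", p), "", reports[p], "")))
  )
  writeLines(md, file.path(out_dir, "report.md"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("workloadcast")),
    seed = config$seed,
    horizon = config$horizon,
    level = config$level,
    model_config = unclass(config$model),
    sim_config = if (is.null(config$input_csv))
      serializable_sim_config(config$sim) else NULL,
    input_csv = config$input_csv,
    selected_epoch = fit$report$selected_epoch,
    artifacts = c("sessions.csv", "evaluation.csv", "forecasts.csv",
                  "importance.csv", "report.md")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sessions = sessions, truth = truth, fit = fit,
                 evaluation = ev, forecasts = fc, importance = bind_rows(imps),
                 reports = reports, out_dir = out_dir))
}

serializable_sim_config <- function(cfg) {
  x <- unclass(cfg)
  x$position_means <- apply(x$position_means, 1, as.list, simplify = FALSE)
  x$kpi_correlation <- apply(x$kpi_correlation, 1, as.list, simplify = FALSE)
  x
}

knit_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.2f", x))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
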