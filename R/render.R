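#' Deterministic coaching-report renderer
#'
#' Turns a forecast and its attribution into a short natural-language
#' summary for coaching staff: the forecast direction relative to the
#' player's recent sessions, the width of the uncertainty band, and the
#' top input channels driving the prediction. Text generation is pluggable:
#' `render_report()` hands a structured context to a backend function, and
#' the bundled [template_backend()] renders it with fixed templates so the
#' output is byte-identical across calls. A different backend (e.g. one
#' calling an external language model) can be supplied with the same
#' contract: a function taking the context list and returning a character
#' scalar.
#'
#' Ties between channel scores are broken by the canonical channel order, so
#' the mention order in the text is deterministic.
#'
#' @param forecast A `workload_forecast` from [forecast_intervals()].
#' @param importance An `importance_map` (any aggregation; it is aggregated
#'   per channel internally when needed).
#' @param sessions Session panel used for the player's recent mean.
#' @param player_id Player the report is about.
#' @param target_kpi KPI the report focuses on; must match the importance
#'   map's target.
#' @param recent_k Number of recent sessions defining the reference mean.
#' @param backend A text backend; see [template_backend()].
#' @return A character scalar.
#' @export
render_report <- function(forecast, importance, sessions, player_id,
                          target_kpi = attr(importance, "target_kpi"),
                          recent_k = 5, backend = template_backend()) {
  stopifnot(is.function(backend))
  if (!identical(target_kpi, attr(importance, "target_kpi"))) {
    abort("`importance` was computed for a different target KPI.",
          class = "workloadcast_parameter_error")
  }
  fc <- as_tibble(forecast) %>%
    filter(.data$player_id == !!player_id, .data$kpi == target_kpi)
  if (nrow(fc) == 0) {
    abort(paste0("No forecast rows for player '", player_id, "' and KPI '",
                 target_kpi, "'."), class = "workloadcast_parameter_error")
  }
  panel <- validate_sessions(sessions)
  hist_vals <- panel[panel$player_id == player_id, ][[target_kpi]]
  recent_mean <- mean(tail(hist_vals, recent_k))

  per_channel <- if (identical(attr(importance, "aggregation"), "per_channel")) {
    as_tibble(importance)
  } else {
    as_tibble(aggregate_importance(importance, by = "channel"))
  }
  if (nrow(per_channel) == 0 || sum(per_channel$score) == 0) {
    top_channels <- character(0)
  } else {
    ord <- order(-per_channel$score,
                 match(per_channel$channel, importance_channels()))
    top_channels <- per_channel$channel[ord][seq_len(min(3, nrow(per_channel)))]
  }
  ctx <- list(
    player_id = player_id,
    target_kpi = target_kpi,
    unit = kpi_units()[[target_kpi]],
    horizon = max(fc$step),
    level = attr(forecast, "level"),
    forecast_mean = mean(fc$mean),
    next_mean = fc$mean[fc$step == 1],
    recent_mean = recent_mean,
    mean_band_width = mean(fc$upper - fc$lower),
    top_channels = top_channels
  )
  backend(ctx)
}

#' @rdname render_report
#' @export
template_backend <- function() {
  function(ctx) {
    fmt <- function(x) formatC(x, format = "f", digits = 1, big.mark = "")
    dir_txt <- if (ctx$forecast_mean < ctx$recent_mean) "below" else
      if (ctx$forecast_mean > ctx$recent_mean) "above" else "level with"
    lines <- c(
      sprintf("Player %s - %s outlook over the next %d session(s).",
              ctx$player_id, ctx$target_kpi, ctx$horizon),
      sprintf(
        "Forecast mean %s %s, %s the recent-session mean of %s %s.",
        fmt(ctx$forecast_mean), ctx$unit, dir_txt, fmt(ctx$recent_mean),
        ctx$unit),
      sprintf("Average %s%% interval width: %s %s.",
              formatC(ctx$level, format = "fg"), fmt(ctx$mean_band_width),
              ctx$unit)
    )
    if (length(ctx$top_channels) == 0) {
      lines <- c(lines, "No attribution available for this prediction.")
    } else {
      lines <- c(lines, sprintf("Main drivers: %s.",
                                paste(ctx$top_channels, collapse = ", ")))
      if (ctx$top_channels[1] == "distance_total" &&
          ctx$forecast_mean < ctx$recent_mean) {
        lines <- c(lines,
                   paste("Recent running volume is the dominant driver and the",
                         "forecast sits below the recent level: possible",
                         "accumulated fatigue; consider load management."))
      }
    }
    paste(lines, collapse = "\n")
  }
}
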