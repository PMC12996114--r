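#' Plot a forecast with its uncertainty band
#'
#' Ribbon-and-line plot of the interval forecast, faceted by KPI, one colour
#' per player. If `sessions` is supplied, the last `history` observed
#' sessions are drawn before the forecast (at negative step numbers).
#'
#' @param object A `workload_forecast` from [forecast_intervals()].
#' @param sessions Optional session panel for historical context.
#' @param history How many trailing observed sessions to show.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot workload_forecast
#' @export
autoplot.workload_forecast <- function(object, sessions = NULL, history = 15,
                                       ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$step)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                      group = .data$player_id),
                         alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean, colour = .data$player_id)) +
    ggplot2::facet_wrap(~kpi, scales = "free_y") +
    ggplot2::labs(x = "forecast step", y = NULL, colour = "player",
                  title = sprintf("%s%% interval forecast",
                                  formatC(attr(object, "level"), format = "fg")))
  if (!is.null(sessions)) {
    hist_df <- validate_sessions(sessions) %>%
      filter(.data$player_id %in% unique(df$player_id)) %>%
      group_by(.data$player_id) %>%
      mutate(step = row_number() - dplyr::n()) %>%
      filter(.data$step > -history) %>%
      ungroup() %>%
      tidyr::pivot_longer(all_of(kpi_names()), names_to = "kpi",
                          values_to = "value")
    p <- p + ggplot2::geom_line(data = hist_df,
                                ggplot2::aes(y = .data$value,
                                             colour = .data$player_id),
                                linetype = "dashed", alpha = 0.6)
  }
  p
}

#' Plot an importance map
#'
#' Heat map of |gradient| scores over (lag, input channel) for per-cell maps,
#' or a bar chart for aggregated maps.
#'
#' @param object An `importance_map`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot importance_map
#' @export
autoplot.importance_map <- function(object, ...) {
  df <- as_tibble(object)
  title <- sprintf("Sensitivity of %s (step %d)", attr(object, "target_kpi"),
                   attr(object, "horizon_step"))
  if (all(c("lag", "channel") %in% names(df))) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$lag,
                                     y = factor(.data$channel,
                                                levels = rev(importance_channels())),
                                     fill = .data$score)) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = "lag (1 = oldest)", y = NULL, fill = "|gradient|",
                    title = title)
  } else {
    key <- if ("channel" %in% names(df)) "channel" else "lag"
    ggplot2::ggplot(df, ggplot2::aes(x = factor(.data[[key]]),
                                     y = .data$score)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = key, y = "aggregated |gradient|", title = title) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }
}

#' Plot training curves
#'
#' Training and validation loss per epoch, with the selected (best
#' validation) epoch marked.
#'
#' @param object A `workload_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot workload_fit
#' @export
autoplot.workload_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$report$history, c("train_loss", "val_loss"),
                            names_to = "split", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$report$selected_epoch,
                        linetype = "dotted") +
    ggplot2::labs(title = "Training history", y = "MSE (normalised scale)")
}

#' Plot a model-comparison report
#'
#' Per-KPI RMSE bars for every evaluated model.
#'
#' @param object A `workload_eval` from [evaluate_models()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot workload_eval
#' @export
autoplot.workload_eval <- function(object, ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$model, y = .data$rmse,
                               fill = .data$model)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~kpi, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "RMSE (pooled over players and steps)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
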