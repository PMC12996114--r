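#' Validate a session panel
#'
#' A session panel is a tibble with one row per player-session holding the
#' canonical identifier, type and position columns plus the six KPI columns
#' (see [kpi_names()]). Validation enforces the structural invariants every
#' downstream function relies on: canonical columns present, KPI values finite
#' and non-negative, `session_type`/`position` drawn from their vocabularies,
#' per-player `session_index` unique, and a single position per player.
#'
#' @param sessions A data frame of player-sessions.
#' @return The validated panel as a tibble, rows ordered by `player_id` then
#'   `session_index`, invisibly usable in a pipe.
#' @examples
#' validate_sessions(simulate_sessions(sim_config(n_sessions = 5))$sessions)
#' @export
validate_sessions <- function(sessions) {
  if (!is.data.frame(sessions)) {
    abort("`sessions` must be a data frame.", class = "workloadcast_schema_error")
  }
  missing_cols <- setdiff(session_columns(), names(sessions))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "workloadcast_schema_error")
  }
  out <- as_tibble(sessions)[session_columns()]
  out$player_id <- as.character(out$player_id)
  out$session_index <- as.integer(out$session_index)
  out$session_type <- as.character(out$session_type)
  out$position <- as.character(out$position)

  bad_type <- !out$session_type %in% session_types()
  if (any(bad_type)) {
    abort(paste0("Invalid session_type in row ", which(bad_type)[1], ": '",
                 out$session_type[which(bad_type)[1]], "'"),
          class = "workloadcast_validation_error")
  }
  bad_pos <- !out$position %in% court_positions()
  if (any(bad_pos)) {
    abort(paste0("Invalid position in row ", which(bad_pos)[1], ": '",
                 out$position[which(bad_pos)[1]], "'"),
          class = "workloadcast_validation_error")
  }
  if (any(is.na(out$session_index)) || any(out$session_index < 0)) {
    abort("session_index must be a non-negative integer.",
          class = "workloadcast_validation_error")
  }
  for (k in kpi_names()) {
    v <- out[[k]]
    if (!is.numeric(v)) {
      abort(paste0("KPI column '", k, "' must be numeric."),
            class = "workloadcast_validation_error")
    }
    bad <- !is.finite(v) | v < 0
    if (any(bad)) {
      abort(paste0("KPI '", k, "' has a negative or non-finite value in row ",
                   which(bad)[1], " (value ", v[which(bad)[1]], ")."),
            class = "workloadcast_validation_error")
    }
  }
  dup <- duplicated(out[c("player_id", "session_index")])
  if (any(dup)) {
    d <- out[which(dup)[1], ]
    abort(paste0("Duplicate (player_id, session_index): ('", d$player_id,
                 "', ", d$session_index, ")."),
          class = "workloadcast_validation_error")
  }
  n_pos <- tapply(out$position, out$player_id, function(p) length(unique(p)))
  if (any(n_pos > 1)) {
    abort(paste0("Player '", names(n_pos)[which(n_pos > 1)[1]],
                 "' has more than one position."),
          class = "workloadcast_validation_error")
  }
  arrange(out, .data$player_id, .data$session_index)
}

#' Read a session panel from CSV
#'
#' Reads the canonical session-summary export format (UTF-8 CSV, header
#' `player_id,session_index,session_type,position,<six KPI columns>`, one row
#' per player-session — the shape of a Kinexon-style per-session export) and
#' validates it. Rows are returned sorted by player then session index.
#'
#' @param path Path to a CSV file.
#' @return A validated session tibble.
#' @seealso [write_sessions()], [validate_sessions()]
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "workloadcast_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  validate_sessions(raw)
}

#' Write a session panel to CSV
#'
#' Writes the canonical CSV with deterministic row order (player then session
#' index), canonical column order, and KPI values formatted to one decimal
#' place so that repeated writes of the same panel are byte-identical.
#'
#' @param sessions A session panel (validated on the way out).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  panel <- validate_sessions(sessions)
  header <- paste(session_columns(), collapse = ",")
  if (nrow(panel) == 0) {
    lines <- header
  } else {
    kpi_cols <- vapply(kpi_names(), function(k) sprintf("%.1f", panel[[k]]),
                       character(nrow(panel)))
    kpi_cols <- matrix(kpi_cols, nrow = nrow(panel))
    body <- paste(panel$player_id, panel$session_index, panel$session_type,
                  panel$position,
                  apply(kpi_cols, 1, paste, collapse = ","), sep = ",")
    lines <- c(header, body)
  }
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    abort(paste0("Cannot open '", path, "' for writing: ",
                 conditionMessage(e)), class = "workloadcast_io_error")
  })
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Per-position KPI summary
#'
#' Arithmetic mean of every KPI within each court position, plus a
#' session-weighted team total (the mean over all records, not the mean of
#' the position means — positions with more recorded sessions weigh more).
#'
#' @param sessions A session panel.
#' @return A tibble with one row per position present plus a final
#'   `"team_total"` row; columns `position`, `n_sessions` and the six KPIs.
#' @examples
#' panel <- simulate_sessions(sim_config(n_sessions = 20))$sessions
#' summarize_by_position(panel)
#' @export
summarize_by_position <- function(sessions) {
  panel <- validate_sessions(sessions)
  if (nrow(panel) == 0) {
    abort("Cannot summarise an empty panel.",
          class = "workloadcast_empty_error")
  }
  by_pos <- panel %>%
    group_by(position = factor(.data$position, levels = court_positions())) %>%
    summarise(n_sessions = dplyr::n(),
              across(all_of(kpi_names()), mean), .groups = "drop") %>%
    arrange(.data$position) %>%
    mutate(position = as.character(.data$position))
  total <- panel %>%
    summarise(position = "team_total", n_sessions = dplyr::n(),
              across(all_of(kpi_names()), mean))
  bind_rows(by_pos, total)
}
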