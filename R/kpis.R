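#' Canonical KPI and schema vocabulary
#'
#' The package works on a fixed set of six per-session key performance
#' indicators (KPIs) summarising the activity a wearable sensor records during
#' one training or one match: total running distance (m), maximal speed
#' (km/h), maximal metabolic power (W), accumulated acceleration load
#' (arbitrary units), number of jumps and number of changes of direction.
#'
#' @return `kpi_names()`: character vector of the six canonical KPI column
#'   names, in canonical order. `court_positions()`: the three sensed court
#'   roles (goalkeepers are not sensed). `session_types()`: the two session
#'   kinds. `session_columns()`: the full canonical CSV column order.
#' @examples
#' kpi_names()
#' session_columns()
#' @export
kpi_names <- function() {
  c("distance_total", "speed_max", "metabolic_power_max",
    "accel_load_accum", "jumps", "changes_of_direction")
}

#' @rdname kpi_names
#' @export
court_positions <- function() c("wing", "back", "pivot")

#' @rdname kpi_names
#' @export
session_types <- function() c("training", "match")

#' @rdname kpi_names
#' @export
session_columns <- function() {
  c("player_id", "session_index", "session_type", "position", kpi_names())
}

# KPI units, used in rendered reports and plot labels
kpi_units <- function() {
  c(distance_total = "m", speed_max = "km/h", metabolic_power_max = "W",
    accel_load_accum = "a.u.", jumps = "count", changes_of_direction = "count")
}
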