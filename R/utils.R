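#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

ts_assert <- function(ok, ..., call. = FALSE) {
  if (!isTRUE(ok)) stop(..., call. = call.)
}

ts_message <- function(..., verbose = getOption("thermosocial.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
}

#' Ordered view-angle categories
#'
#' The seven head-orientation categories used when coding thermal pictures,
#' ordered from the reference orientation (`facing`, head-camera axis within
#' 45 degrees) to full profile. `facing` is always the first level and the
#' reference for angle-bias correction.
#'
#' @return Character vector of the seven angle labels.
#' @export
ts_angle_levels <- function() {
  c("facing",
    "quarter_left", "quarter_right",
    "half_left", "half_right",
    "profile_left", "profile_right")
}

#' Event-type labels and their thermal-signature groups
#'
#' The thirteen social event types coded in the field plus the resting
#' `baseline`, together with the default mapping onto the three thermal
#' signature groups: `A` (cooperative), `B` (competitive) and `C`
#' (coerced-cooperation / mixed). Grooming is a single event type; the
#' subject's role (given / received / mutual) is carried in a separate
#' column of the event table.
#'
#' @return Named character vector: names are event types, values are group
#'   labels in `{"A", "B", "C", "baseline"}`.
#' @export
ts_event_cluster_map <- function() {
  c(grooming          = "A",
    playing           = "A",
    patrolling        = "A",
    female_inspection = "A",
    dominant_arrival  = "B",
    display           = "B",
    copulation        = "B",
    hearing_screams   = "B",
    aggression        = "B",
    feeding           = "B",
    meat_solicitation = "C",
    female_solicitation = "C",
    snake             = "C",
    baseline          = "baseline")
}
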