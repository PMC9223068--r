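#' Fusion configuration
#'
#' The presence and movement streams carry no shared clock semantics beyond
#' timestamps, so "sitting and there is movement" is given a sliding-recency
#' meaning: movement counts as active at time `t` if a `MOVEMENT_EVENT`
#' occurred in `(t - movement_window_ms, t]`.
#'
#' @param movement_window_ms Recency window in ms (default 2000).
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(movement_window_ms = 2000) {
  stopifnot(movement_window_ms > 0)
  structure(list(movement_window_ms = movement_window_ms), class = "fusion_config")
}

#' Single risk decision from a stable position and movement flag
#'
#' The two risk situations: the bed is empty (`NO_PRESENCE` — the wearer
#' exited, alarm regardless of movement), or the wearer sits on a bed edge
#' while movement is detected (an intention to exit). Lying positions never
#' alarm.
#'
#' @param presence A stable (debounced) position label; `NOT_RECOGNIZED` is
#'   a contract violation.
#' @param movement_active Logical: was movement recently detected?
#' @return `"BED_EXIT"`, `"EXIT_INTENT"`, or `NA_character_` (no alarm).
#' @examples
#' fuse_risk("NO_PRESENCE", FALSE)           # BED_EXIT
#' fuse_risk("SITTING_IN_RIGHT_EDGE", TRUE)  # EXIT_INTENT
#' @export
fuse_risk <- function(presence, movement_active) {
  if (!presence %in% setdiff(POSITION_LEVELS, "NOT_RECOGNIZED")) {
    abort("fuse_risk requires a stable position (NOT_RECOGNIZED is not allowed)",
          class = "bedwatch_contract_error")
  }
  if (presence == "NO_PRESENCE") return("BED_EXIT")
  if (presence %in% c("SITTING_IN_LEFT_EDGE", "SITTING_IN_RIGHT_EDGE") &&
      isTRUE(movement_active)) {
    return("EXIT_INTENT")
  }
  NA_character_
}

#' Fuse presence and movement event streams into risk alarms
#'
#' Merges the two time-ordered streams and applies [fuse_risk()] at every
#' presence change and at every movement event, with movement considered
#' active for `movement_window_ms` after each `MOVEMENT_EVENT`. A presence
#' episode (the interval during which the stable position is unchanged)
#' raises at most one alarm; the alarm re-arms when the position changes.
#'
#' @param presence_events Event tibble of `PRESENCE` rows.
#' @param movement_events Event tibble of `MOVEMENT_EVENT` rows.
#' @param config A [fusion_config()].
#' @return An event tibble of `ALARM` rows with reasons `BED_EXIT` /
#'   `EXIT_INTENT`.
#' @examples
#' p <- event(10000, "PRESENCE", position = "NO_PRESENCE")
#' monitor_activity(p, empty_events())
#' @export
monitor_activity <- function(presence_events, movement_events,
                             config = fusion_config()) {
  pres <- presence_events[presence_events$kind == "PRESENCE", , drop = FALSE]
  mov <- movement_events[movement_events$kind == "MOVEMENT_EVENT", , drop = FALSE]
  merged <- bind_rows(
    tibble(t_ms = pres$t_ms, what = "presence", position = pres$position),
    tibble(t_ms = mov$t_ms, what = "movement", position = NA_character_)
  )
  # at equal timestamps apply the position change before the movement event
  merged <- merged[order(merged$t_ms, merged$what != "movement", decreasing = FALSE), ]
  merged <- merged[order(merged$t_ms, match(merged$what, c("presence", "movement"))), ]

  alarms <- empty_events()
  position <- NA_character_
  episode_alarmed <- FALSE
  mov_times <- mov$t_ms
  w <- config$movement_window_ms
  active_at <- function(t) any(mov_times > t - w & mov_times <= t)

  for (i in seq_len(nrow(merged))) {
    t <- merged$t_ms[i]
    if (merged$what[i] == "presence") {
      position <- merged$position[i]
      episode_alarmed <- FALSE
    }
    if (is.na(position) || episode_alarmed) next
    reason <- fuse_risk(position, active_at(t))
    if (!is.na(reason)) {
      alarms <- bind_rows(alarms, event(t, "ALARM", reason = reason, source = "fusion"))
      episode_alarmed <- TRUE
    }
  }
  alarms
}
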