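#' Bed-presence configuration
#'
#' Parameters of the rule-based bed-position classifier and its debouncer.
#' `near_zero_eps` operationalises "near zero" (a strip reading at or below
#' it counts as unloaded); `large_diff_delta` operationalises "a large
#' difference" between two strips; `min_hold_ms` is how long a raw position
#' must persist before it is accepted as the stable posture (transitions
#' between postures produce unreliable readings, so short-lived labels are
#' discarded).
#'
#' @param full_scale ADC full scale of the pressure strips (default 1023).
#' @param near_zero_eps Counts at or below which a strip reads "near zero"
#'   (default 5% of full scale).
#' @param large_diff_delta Counts at or above which a difference between two
#'   strips is "large" (default 40% of full scale).
#' @param min_hold_ms Debounce hold; a raw label must persist strictly
#'   longer than this before being emitted (default 1000 ms).
#' @return A `presence_config` list.
#' @export
presence_config <- function(full_scale = 1023,
                            near_zero_eps = 0.05 * full_scale,
                            large_diff_delta = 0.40 * full_scale,
                            min_hold_ms = 1000) {
  stopifnot(near_zero_eps >= 0, near_zero_eps < large_diff_delta,
            large_diff_delta <= full_scale, min_hold_ms > 0)
  structure(
    list(full_scale = full_scale, near_zero_eps = near_zero_eps,
         large_diff_delta = large_diff_delta, min_hold_ms = min_hold_ms),
    class = "presence_config"
  )
}

#' Classify raw pressure readings into bed positions
#'
#' Applies the rule cascade over the three strip readings, in order, first
#' match wins: all strips near zero is `NO_PRESENCE`; the middle strip
#' dominating both edges (with both middle-to-edge separations exceeding the
#' edge-to-edge one) is `LYING_IN_MIDDLE`; one edge strip dominating with
#' the opposite edge near zero and a large edge-to-middle gap is a SITTING
#' position; middle dominating an elevated edge is the corresponding LYING
#' edge position. Differences are absolute, inequalities strict; readings
#' matching no rule (including exact ties) are `NOT_RECOGNIZED`.
#'
#' @param stream A `pressure_stream` tibble (or any data frame with columns
#'   `left`, `middle`, `right`; `t_ms` optional).
#' @param config A [presence_config()].
#' @return A tibble with columns `t_ms` (if supplied) and `position`.
#' @examples
#' classify_pressure(pressure_stream(0, 0, 0, 0))  # NO_PRESENCE
#' @export
classify_pressure <- function(stream, config = presence_config()) {
  if (!is.data.frame(stream) ||
      !all(c("left", "middle", "right") %in% names(stream))) {
    abort("classify_pressure needs left/middle/right columns",
          class = "bedwatch_validation_error")
  }
  l <- stream$left; m <- stream$middle; r <- stream$right
  if (any(c(l, m, r) < 0)) {
    abort("pressure counts must be non-negative", class = "bedwatch_validation_error")
  }
  eps <- config$near_zero_eps
  delta <- config$large_diff_delta
  d <- function(a, b) abs(a - b)

  pos <- rep("NOT_RECOGNIZED", length(l))
  todo <- rep(TRUE, length(l))
  take <- function(cond, label) {
    hit <- todo & cond
    pos[hit] <<- label
    todo[hit] <<- FALSE
  }
  take(m <= eps & l <= eps & r <= eps, "NO_PRESENCE")
  take(m > r & m > l & d(r, m) > d(l, r) & d(l, m) > d(l, r), "LYING_IN_MIDDLE")
  take(l > r & l > m & r <= eps & d(l, m) >= delta, "SITTING_IN_LEFT_EDGE")
  take(l > r & m > l & d(l, m) < d(r, l), "LYING_IN_LEFT_EDGE")
  take(r > l & r > m & l <= eps & d(r, m) >= delta, "SITTING_IN_RIGHT_EDGE")
  take(r > l & m > r & d(r, m) < d(r, l), "LYING_IN_RIGHT_EDGE")

  out <- tibble(position = pos)
  if ("t_ms" %in% names(stream)) out <- tibble(t_ms = stream$t_ms, position = pos)
  out
}

#' Debounce a raw position stream into stable presence events
#'
#' `NOT_RECOGNIZED` labels are dropped (no change of position is considered).
#' A new position becomes stable — and is emitted as a `PRESENCE` event —
#' only once the same raw label has persisted continuously for strictly
#' longer than `min_hold_ms`, measured from the first sample of the run;
#' shorter excursions are suppressed and the previous stable position is
#' retained. The event is stamped at the sample that completes the hold.
#'
#' @param labels Tibble with time-ordered `t_ms` and `position` columns (as
#'   from [classify_pressure()]).
#' @param config A [presence_config()].
#' @param source Sensor identifier written into the events.
#' @return An event tibble of `PRESENCE` rows; consecutive events always
#'   differ in position and never carry `NOT_RECOGNIZED`.
#' @export
debounce_positions <- function(labels, config = presence_config(),
                               source = "bed") {
  keep <- labels$position != "NOT_RECOGNIZED"
  t <- labels$t_ms[keep]
  p <- labels$position[keep]
  events <- empty_events()
  stable <- NA_character_
  run_label <- NA_character_
  run_start <- NA_integer_
  for (i in seq_along(t)) {
    if (is.na(run_label) || p[i] != run_label) {
      run_label <- p[i]
      run_start <- t[i]
    }
    if (!identical(run_label, stable) && (t[i] - run_start) > config$min_hold_ms) {
      stable <- run_label
      events <- bind_rows(events,
                          event(t[i], "PRESENCE", position = stable, source = source))
    }
  }
  events
}

#' Full bed-presence pipeline: pressure stream to stable presence events
#'
#' Classifies every pressure sample with the rule cascade, then debounces
#' the raw label stream. If an [event_bus()] is supplied the events are also
#' published on the `"bed-presence"` topic.
#'
#' @param stream A `pressure_stream` tibble.
#' @param config A [presence_config()].
#' @param bus Optional `event_bus` to publish on.
#' @param source Sensor identifier written into the events.
#' @return An event tibble of stable `PRESENCE` events.
#' @examples
#' ps <- sim_pressure_sequence("LYING_IN_MIDDLE", hold_ms = 3000, seed = 1)
#' detect_presence(ps)
#' @export
detect_presence <- function(stream, config = presence_config(), bus = NULL,
                            source = "bed") {
  stream <- validate_pressure_stream(stream, full_scale = config$full_scale)
  raw <- classify_pressure(stream, config)
  events <- debounce_positions(raw, config, source = source)
  if (!is.null(bus)) {
    bus_register(bus, "bed-presence")
    if (nrow(events) > 0) bus_publish(bus, "bed-presence", events)
  }
  events
}
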