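#' Movement-detector configuration
#'
#' Thresholds of the stand-up/walk posture test on single accelerometer
#' samples. With the sensor worn at the waist, the x axis is vertical when
#' upright: standing shows x above ~0.9 g with z (the into-body horizontal
#' axis) inside +/-0.4 g, while lying shows x near 0 and z near 1 g. The y
#' component is ignored — it only discriminates the exit side, which is
#' irrelevant for raising an alarm.
#'
#' @param x_min Lower bound on `ax` in g (strict, default 0.9).
#' @param z_abs_max Bound on `|az|` in g (strict, default 0.4).
#' @param rearm_ms Minimum spacing between emitted movement events
#'   (default 2000 ms); the posture test itself holds true continuously
#'   while standing, so emissions are rate-limited.
#' @return A `motion_config` list.
#' @export
motion_config <- function(x_min = 0.9, z_abs_max = 0.4, rearm_ms = 2000) {
  stopifnot(x_min > 0, z_abs_max > 0, rearm_ms > 0)
  structure(list(x_min = x_min, z_abs_max = z_abs_max, rearm_ms = rearm_ms),
            class = "motion_config")
}

#' Stand-up posture test on accelerometer samples
#'
#' `TRUE` iff `ax > x_min` and `-z_abs_max < az < z_abs_max` (strict
#' inequalities). Depends only on the x and z components. Vectorised.
#'
#' @param stream An `imu_stream` tibble (or data frame with `ax`, `az`).
#' @param config A [motion_config()].
#' @return Logical vector, one element per sample.
#' @examples
#' is_moving(imu_stream(0, ax = 0.95, az = 0))  # TRUE
#' @export
is_moving <- function(stream, config = motion_config()) {
  stream$ax > config$x_min &
    stream$az > -config$z_abs_max & stream$az < config$z_abs_max
}

#' Emit movement events from an IMU stream
#'
#' Scans the stream with [is_moving()] and emits a `MOVEMENT_EVENT` at each
#' sample where the posture test holds and no event was emitted within the
#' preceding `rearm_ms`. A continuously standing wearer therefore produces
#' one event per rearm window rather than one per sample, while a lying or
#' rolling wearer produces none.
#'
#' @param stream An `imu_stream` tibble.
#' @param config A [motion_config()].
#' @param bus Optional [event_bus()]; events are published on `"movement"`.
#' @param source Sensor identifier written into the events.
#' @return An event tibble of `MOVEMENT_EVENT` rows.
#' @examples
#' bx <- sim_bed_exit("left", seed = 1)
#' detect_motion(bx$imu)
#' @export
detect_motion <- function(stream, config = motion_config(), bus = NULL,
                          source = "imu") {
  stream <- validate_imu_stream(stream)
  moving <- is_moving(stream, config)
  t <- stream$t_ms
  emit_t <- integer()
  last <- -Inf
  for (i in which(moving)) {
    if (t[i] - last >= config$rearm_ms) {
      emit_t <- c(emit_t, t[i])
      last <- t[i]
    }
  }
  events <- if (length(emit_t) > 0) {
    bind_rows(map(emit_t, ~ event(.x, "MOVEMENT_EVENT", source = source)))
  } else {
    empty_events()
  }
  if (!is.null(bus)) {
    bus_register(bus, "movement")
    if (nrow(events) > 0) bus_publish(bus, "movement", events)
  }
  events
}
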