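#' Fall-detector configuration
#'
#' Thresholds and timing of the on-sensor fall state machine. A candidate
#' fall is a peak in the acceleration signal vector magnitude above
#' `fall_threshold_g` (default 2.5 g), followed by a 1 s capture window and a
#' 1.5 s quiescence check: any new supra-threshold peak during the check
#' cancels the candidate and restarts the capture (the wearer is likely
#' running or otherwise active, not fallen).
#'
#' @param fall_threshold_g Peak threshold on the signal vector magnitude, in
#'   g. Comparisons are strict (`>`); a sample exactly at threshold does not
#'   trigger.
#' @param post_peak_window_ms Capture window after the triggering peak (ms).
#' @param post_fall_quiet_ms Quiescence window that must elapse without a new
#'   peak before the fall event is emitted (ms).
#' @param rate_hz Nominal sampling rate of the IMU stream (>= 30 Hz).
#' @return A `fall_config` list.
#' @export
fall_config <- function(fall_threshold_g = 2.5, post_peak_window_ms = 1000,
                        post_fall_quiet_ms = 1500, rate_hz = 50) {
  stopifnot(fall_threshold_g > 0, post_peak_window_ms > 0,
            post_fall_quiet_ms > 0, rate_hz >= 30)
  structure(
    list(
      fall_threshold_g = fall_threshold_g,
      post_peak_window_ms = post_peak_window_ms,
      post_fall_quiet_ms = post_fall_quiet_ms,
      rate_hz = rate_hz
    ),
    class = "fall_config"
  )
}

#' Initial state of the fall state machine
#'
#' The machine has three phases. `SAMPLING`: waiting for a supra-threshold
#' peak; the sample log is empty. `POST_PEAK`: a peak was seen; samples are
#' appended to the log until the capture deadline passes. `POST_FALL`:
#' quiescence check; a new peak clears the log and restarts the capture,
#' while an uneventful deadline emits a `FALL_EVENT` carrying the log.
#'
#' @return A `detector_state` list with fields `phase`, `time_reference_ms`
#'   and `log` (an `imu_stream` tibble).
#' @export
detector_init <- function() {
  structure(
    list(phase = "SAMPLING", time_reference_ms = NA_integer_,
         log = imu_stream(integer(), double())),
    class = "detector_state"
  )
}

#' Advance the fall state machine by one IMU sample
#'
#' Pure transition function of the edge state machine: given the current
#' state and the next sample, returns the new state and, when a candidate
#' fall completes its quiescence check, a `FALL_EVENT` carrying the captured
#' window. Deadline comparisons are strict (`t > time_reference`).
#'
#' @param state A `detector_state`, from [detector_init()] or a previous call.
#' @param sample One-row `imu_stream` tibble; its `t_ms` must exceed every
#'   logged timestamp.
#' @param config A [fall_config()].
#' @return A list with elements `state` (the new `detector_state`) and
#'   `event` (`NULL`, or a one-row `FALL_EVENT` tibble whose window is
#'   attached as attribute `"window"`).
#' @export
fall_step <- function(state, sample, config = fall_config()) {
  stopifnot(inherits(state, "detector_state"))
  if (nrow(state$log) > 0 && sample$t_ms <= max(state$log$t_ms)) {
    abort("out-of-order sample fed to fall_step", class = "bedwatch_validation_error")
  }
  svm <- signal_magnitude(sample$ax, sample$ay, sample$az)
  t <- sample$t_ms
  out_event <- NULL

  if (state$phase == "SAMPLING") {
    if (svm > config$fall_threshold_g) {
      state$phase <- "POST_PEAK"
      state$time_reference_ms <- t + config$post_peak_window_ms
      state$log <- sample
    }
  } else if (state$phase == "POST_PEAK") {
    state$log <- bind_rows(state$log, sample)
    if (t > state$time_reference_ms) {
      state$phase <- "POST_FALL"
      state$time_reference_ms <- t + config$post_fall_quiet_ms
    }
  } else { # POST_FALL
    if (svm > config$fall_threshold_g) {
      state$phase <- "POST_PEAK"
      state$time_reference_ms <- t + config$post_peak_window_ms
      state$log <- sample
    } else if (t > state$time_reference_ms) {
      ev <- event(t, "FALL_EVENT", source = "imu")
      attr(ev, "window") <- validate_imu_stream(state$log)
      out_event <- ev
      state$phase <- "SAMPLING"
      state$time_reference_ms <- NA_integer_
      state$log <- imu_stream(integer(), double())
    }
  }
  list(state = state, event = out_event)
}

#' Run the fall state machine over a whole IMU stream
#'
#' Replays [fall_step()] sample by sample and collects the emitted
#' `FALL_EVENT`s. Each event row carries its captured window in the
#' list-column `window`.
#'
#' @param stream An `imu_stream` tibble.
#' @param config A [fall_config()].
#' @return A tibble of fall events with columns `t_ms, kind, position,
#'   reason, source` and a list-column `window` of captured `imu_stream`s.
#' @examples
#' trace <- sim_fall_trace("forward", seed = 1)
#' detect_falls(trace)
#' @export
detect_falls <- function(stream, config = fall_config()) {
  stream <- validate_imu_stream(stream)
  n <- nrow(stream)
  svm <- signal_magnitude(stream$ax, stream$ay, stream$az)
  t <- stream$t_ms
  thr <- config$fall_threshold_g

  # Inlined state loop (same transitions as fall_step) so long traces and
  # property sweeps stay fast; fall_step() is the reference implementation
  # and the two are checked against each other in the test suite.
  phase <- 0L # 0 SAMPLING, 1 POST_PEAK, 2 POST_FALL
  deadline <- NA_integer_
  log_start <- NA_integer_
  log_end <- NA_integer_
  ev_t <- integer()
  ev_start <- integer()
  ev_end <- integer()

  for (i in seq_len(n)) {
    if (phase == 0L) {
      if (svm[i] > thr) {
        phase <- 1L
        deadline <- t[i] + config$post_peak_window_ms
        log_start <- i; log_end <- i
      }
    } else if (phase == 1L) {
      log_end <- i
      if (t[i] > deadline) {
        phase <- 2L
        deadline <- t[i] + config$post_fall_quiet_ms
      }
    } else {
      if (svm[i] > thr) {
        phase <- 1L
        deadline <- t[i] + config$post_peak_window_ms
        log_start <- i; log_end <- i
      } else if (t[i] > deadline) {
        ev_t <- c(ev_t, t[i])
        ev_start <- c(ev_start, log_start)
        ev_end <- c(ev_end, log_end)
        phase <- 0L
        deadline <- NA_integer_
        log_start <- NA_integer_; log_end <- NA_integer_
      }
    }
  }

  if (length(ev_t) == 0) {
    out <- empty_events()
    out$window <- list()
    return(out)
  }
  out <- bind_rows(lapply(ev_t, function(tt) event(tt, "FALL_EVENT", source = "imu")))
  out$window <- map2(ev_start, ev_end, function(a, b) {
    validate_imu_stream(stream[a:b, ])
  })
  out
}

#' Extract the candidate window around the strongest peak of a trace
#'
#' Training data are labelled whole traces, while the classifier consumes
#' the window the sensor would have captured. This helper takes the window
#' starting at the sample with the highest signal vector magnitude and
#' spanning `window_ms` — the same span the state machine logs after a
#' triggering peak — so that sub-threshold activities (which never trigger
#' the state machine) can still contribute training windows.
#'
#' @param stream An `imu_stream` tibble.
#' @param window_ms Window span in ms (default 1000, the capture window).
#' @return An `imu_stream` tibble covering the window.
#' @export
trace_window <- function(stream, window_ms = 1000) {
  stream <- validate_imu_stream(stream)
  if (nrow(stream) == 0) {
    abort("cannot window an empty trace", class = "bedwatch_domain_error")
  }
  svm <- signal_magnitude(stream$ax, stream$ay, stream$az)
  peak <- which.max(svm)
  t0 <- stream$t_ms[peak]
  validate_imu_stream(stream[stream$t_ms >= t0 & stream$t_ms <= t0 + window_ms, ])
}
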