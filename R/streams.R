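#' Construct and validate an IMU sample stream
#'
#' An IMU stream is a tibble with one row per reading of the waist-worn
#' inertial sensor: integer millisecond timestamps, tri-axial acceleration in
#' g and tri-axial angular velocity in deg/s. The axis convention follows the
#' sensor's worn orientation: x points upward (perpendicular to the ground
#' when standing), y to the wearer's left, z horizontally into the body.
#'
#' @param t_ms Integer milliseconds since stream start; strictly increasing.
#' @param ax,ay,az Acceleration along each axis, in g.
#' @param gx,gy,gz Angular velocity about each axis, in deg/s.
#' @return A tibble of class `imu_stream` with columns
#'   `t_ms, ax, ay, az, gx, gy, gz`.
#' @examples
#' imu_stream(t_ms = c(0, 20), ax = c(1, 1), ay = 0, az = 0,
#'            gx = 0, gy = 0, gz = 0)
#' @export
imu_stream <- function(t_ms, ax, ay = 0, az = 0, gx = 0, gy = 0, gz = 0) {
  out <- tibble(
    t_ms = as.integer(t_ms),
    ax = as.double(ax), ay = as.double(ay), az = as.double(az),
    gx = as.double(gx), gy = as.double(gy), gz = as.double(gz)
  )
  validate_imu_stream(out)
}

#' @rdname imu_stream
#' @param x A data frame to validate.
#' @export
validate_imu_stream <- function(x) {
  cols <- c("t_ms", "ax", "ay", "az", "gx", "gy", "gz")
  check_stream_frame(x, cols, "IMU")
  x <- as_tibble(x)[cols]
  class(x) <- unique(c("imu_stream", class(x)))
  x
}

#' Construct and validate a bed-pressure sample stream
#'
#' One row per simultaneous reading of the three pressure strips placed
#' across the bed width under the mattress (left edge, centre, right edge).
#' Readings are raw ADC counts in `[0, full_scale]`.
#'
#' @param t_ms Integer milliseconds; strictly increasing.
#' @param left,middle,right Non-negative raw counts per strip.
#' @param full_scale ADC full scale used for range validation (default 1023).
#' @return A tibble of class `pressure_stream` with columns
#'   `t_ms, left, middle, right`.
#' @export
pressure_stream <- function(t_ms, left, middle, right, full_scale = 1023) {
  out <- tibble(
    t_ms = as.integer(t_ms),
    left = as.double(left), middle = as.double(middle),
    right = as.double(right)
  )
  validate_pressure_stream(out, full_scale = full_scale)
}

#' @rdname pressure_stream
#' @param x A data frame to validate.
#' @export
validate_pressure_stream <- function(x, full_scale = 1023) {
  cols <- c("t_ms", "left", "middle", "right")
  check_stream_frame(x, cols, "pressure")
  vals <- unlist(x[c("left", "middle", "right")], use.names = FALSE)
  if (any(vals < 0)) {
    abort("pressure counts must be non-negative", class = "bedwatch_validation_error")
  }
  if (any(vals > full_scale)) {
    abort(
      sprintf("pressure counts exceed full_scale (%s)", full_scale),
      class = "bedwatch_validation_error"
    )
  }
  x <- as_tibble(x)[cols]
  class(x) <- unique(c("pressure_stream", class(x)))
  x
}

check_stream_frame <- function(x, cols, what) {
  if (!is.data.frame(x)) {
    abort(sprintf("%s stream must be a data frame", what),
          class = "bedwatch_validation_error")
  }
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(
      sprintf("%s stream is missing columns: %s", what,
              paste(missing, collapse = ", ")),
      class = "bedwatch_validation_error"
    )
  }
  vals <- unlist(x[setdiff(cols, "t_ms")], use.names = FALSE)
  if (length(vals) && any(!is.finite(vals))) {
    abort(sprintf("%s stream contains non-finite values", what),
          class = "bedwatch_validation_error")
  }
  if (nrow(x) > 1 && any(diff(x$t_ms) <= 0)) {
    bad <- which(diff(x$t_ms) <= 0)[1] + 1
    abort(
      sprintf("%s stream timestamps must be strictly increasing (row %d)", what, bad),
      class = "bedwatch_validation_error"
    )
  }
  invisible(x)
}

#' Acceleration signal vector magnitude
#'
#' The Euclidean norm `sqrt(ax^2 + ay^2 + az^2)` of a tri-axial acceleration
#' reading, in g. The fall state machine compares this magnitude against the
#' 2.5 g fall threshold; the same form is applied to angular velocity for the
#' gyroscope spectral feature. Vectorised over its arguments.
#'
#' @param ax,ay,az Acceleration components in g (or angular velocity in
#'   deg/s); must be finite.
#' @return Non-negative magnitude, same length as the inputs.
#' @examples
#' signal_magnitude(0.6, 0.8, 0) # 1
#' @export
signal_magnitude <- function(ax, ay, az) {
  if (any(!is.finite(c(ax, ay, az)))) {
    abort("signal_magnitude requires finite inputs", class = "bedwatch_domain_error")
  }
  sqrt(ax^2 + ay^2 + az^2)
}

# ---- CSV dialects ----------------------------------------------------------

IMU_CSV_HEADER <- c("t_ms", "ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps")
PRESSURE_CSV_HEADER <- c("t_ms", "left", "middle", "right")

#' Read and write IMU streams as CSV
#'
#' The IMU CSV dialect has header
#' `t_ms,ax_g,ay_g,az_g,gx_dps,gy_dps,gz_dps`, comma separators, UTF-8 and LF
#' line endings. Floats are written with 6 significant digits, which exceeds
#' the sensor resolution, so a write/read round trip is stable.
#'
#' @param path File path.
#' @return `read_imu_csv()` returns a validated `imu_stream` tibble;
#'   `write_imu_csv()` returns `path` invisibly.
#' @export
read_imu_csv <- function(path) {
  df <- read_stream_csv(path, IMU_CSV_HEADER, "IMU")
  names(df) <- c("t_ms", "ax", "ay", "az", "gx", "gy", "gz")
  validate_imu_stream(df)
}

#' @rdname read_imu_csv
#' @param stream An `imu_stream` tibble.
#' @export
write_imu_csv <- function(stream, path) {
  stream <- validate_imu_stream(stream)
  write_stream_csv(stream, path, IMU_CSV_HEADER)
}

#' Read and write pressure streams as CSV
#'
#' Dialect: header `t_ms,left,middle,right`, comma separators, UTF-8, LF.
#'
#' @param path File path.
#' @param full_scale ADC full scale for validation (default 1023).
#' @return `read_pressure_csv()` returns a validated `pressure_stream`;
#'   `write_pressure_csv()` returns `path` invisibly.
#' @export
read_pressure_csv <- function(path, full_scale = 1023) {
  df <- read_stream_csv(path, PRESSURE_CSV_HEADER, "pressure")
  validate_pressure_stream(df, full_scale = full_scale)
}

#' @rdname read_pressure_csv
#' @param stream A `pressure_stream` tibble.
#' @export
write_pressure_csv <- function(stream, path) {
  stream <- validate_pressure_stream(stream)
  write_stream_csv(stream, path, PRESSURE_CSV_HEADER)
}

read_stream_csv <- function(path, header, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s CSV not found: %s", what, path), class = "bedwatch_io_error")
  }
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  got <- strsplit(first, ",", fixed = TRUE)[[1]]
  if (!identical(trimws(got), header)) {
    abort(
      sprintf("%s CSV header mismatch: expected '%s', got '%s'",
              what, paste(header, collapse = ","), first),
      class = "bedwatch_parse_error"
    )
  }
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric", encoding = "UTF-8"),
    warning = function(w) abort(
      sprintf("malformed %s CSV: %s", what, conditionMessage(w)),
      class = "bedwatch_parse_error"
    ),
    error = function(e) abort(
      sprintf("malformed %s CSV: %s", what, conditionMessage(e)),
      class = "bedwatch_parse_error"
    )
  )
  bad <- which(!stats::complete.cases(df))
  if (length(bad) > 0) {
    abort(
      sprintf("malformed %s CSV row at line %d of %s", what, bad[1] + 1L, path),
      class = "bedwatch_parse_error"
    )
  }
  df$t_ms <- as.integer(df$t_ms)
  as_tibble(df)
}

write_stream_csv <- function(stream, path, header) {
  df <- as.data.frame(stream)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) {
    trimws(formatC(signif(v, 6), format = "g", digits = 6))
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con, sep = "\n")
  utils::write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE, eol = "\n")
  invisible(path)
}

# ---- Events ----------------------------------------------------------------

#' Build a typed system event tibble
#'
#' Events are the lingua franca of the detectors: `FALL_EVENT` (candidate
#' fall window captured), `MOVEMENT_EVENT` (stand-up posture detected),
#' `PRESENCE` (stable bed position, carries `position`), and `ALARM`
#' (caregiver notification, carries `reason`: `BED_EXIT`, `EXIT_INTENT` or
#' `FALL`). Event logs are time-ordered tibbles with columns
#' `t_ms, kind, position, reason, source`.
#'
#' @param t_ms Event time in integer milliseconds.
#' @param kind One of `FALL_EVENT`, `MOVEMENT_EVENT`, `PRESENCE`, `ALARM`.
#' @param position Bed position; required iff `kind == "PRESENCE"`.
#' @param reason Alarm reason; required iff `kind == "ALARM"`.
#' @param source Free-form sensor identifier.
#' @return A one-row event tibble.
#' @export
event <- function(t_ms, kind, position = NA_character_, reason = NA_character_,
                  source = NA_character_) {
  kind <- match.arg(kind, EVENT_KINDS)
  if (kind == "PRESENCE") {
    if (is.na(position) || !position %in% POSITION_LEVELS) {
      abort("PRESENCE events require a valid position", class = "bedwatch_validation_error")
    }
  } else if (!is.na(position)) {
    abort(sprintf("%s events must not carry a position", kind),
          class = "bedwatch_validation_error")
  }
  if (kind == "ALARM") {
    if (is.na(reason) || !reason %in% ALARM_REASONS) {
      abort("ALARM events require a valid reason", class = "bedwatch_validation_error")
    }
  } else if (!is.na(reason)) {
    abort(sprintf("%s events must not carry a reason", kind),
          class = "bedwatch_validation_error")
  }
  tibble(
    t_ms = as.integer(t_ms), kind = kind,
    position = as.character(position), reason = as.character(reason),
    source = as.character(source)
  )
}

#' An empty, correctly typed event log
#' @return A zero-row event tibble.
#' @export
empty_events <- function() {
  tibble(
    t_ms = integer(), kind = character(), position = character(),
    reason = character(), source = character()
  )
}

#' Read and write event logs as JSON lines
#'
#' One JSON object per line with keys `t_ms`, `kind` and, when present,
#' `position`, `reason`, `source`; absent keys are omitted on write and
#' restored as `NA` on read.
#'
#' @param path File path.
#' @return `read_events_jsonl()` returns an event tibble;
#'   `write_events_jsonl()` returns `path` invisibly.
#' @export
read_events_jsonl <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("event log not found: %s", path), class = "bedwatch_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_events())
  rows <- map(lines, function(l) {
    obj <- jsonlite::fromJSON(l)
    tibble(
      t_ms = as.integer(obj$t_ms),
      kind = as.character(obj$kind),
      position = as.character(obj$position %||% NA_character_),
      reason = as.character(obj$reason %||% NA_character_),
      source = as.character(obj$source %||% NA_character_)
    )
  })
  bind_rows(rows)
}

#' @rdname read_events_jsonl
#' @param events An event tibble.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      row <- as.list(events[i, ])
      row <- row[!vapply(row, function(v) is.na(v), logical(1))]
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con, sep = "\n")
    }
  }
  invisible(path)
}

# ---- In-process event bus --------------------------------------------------

#' In-process publish/subscribe event bus
#'
#' A minimal ordered, lossless bus that stands in for the network transport
#' between services: detectors publish typed events on named topics, and
#' consumers drain them in publication order. Topics must be registered
#' before use.
#'
#' @param topics Character vector of topic names to register.
#' @return An `event_bus` object.
#' @examples
#' bus <- event_bus(c("fall", "presence"))
#' bus_publish(bus, "fall", event(100, "FALL_EVENT"))
#' bus_collect(bus, "fall")
#' @export
event_bus <- function(topics = character()) {
  bus <- new.env(parent = emptyenv())
  bus$topics <- new.env(parent = emptyenv())
  for (tp in topics) bus_register(structure(bus, class = "event_bus"), tp)
  structure(bus, class = "event_bus")
}

#' @rdname event_bus
#' @param bus An `event_bus`.
#' @param topic Topic name.
#' @export
bus_register <- function(bus, topic) {
  stopifnot(inherits(bus, "event_bus"))
  if (!is.null(bus$topics[[topic]])) return(invisible(bus))
  bus$topics[[topic]] <- list(events = empty_events(), cursor = 0L)
  invisible(bus)
}

#' @rdname event_bus
#' @param events Event tibble (one or more rows) to publish.
#' @export
bus_publish <- function(bus, topic, events) {
  st <- bus_state(bus, topic)
  st$events <- bind_rows(st$events, events)
  bus$topics[[topic]] <- st
  invisible(bus)
}

#' @rdname event_bus
#' @description `bus_collect()` returns, in publication order, the events
#'   published on a topic since it was last drained.
#' @export
bus_collect <- function(bus, topic) {
  st <- bus_state(bus, topic)
  new <- st$events[seq_len(nrow(st$events)) > st$cursor, , drop = FALSE]
  st$cursor <- nrow(st$events)
  bus$topics[[topic]] <- st
  new
}

bus_state <- function(bus, topic) {
  stopifnot(inherits(bus, "event_bus"))
  st <- bus$topics[[topic]]
  if (is.null(st)) {
    abort(sprintf("unknown bus topic: %s", topic), class = "bedwatch_config_error")
  }
  st
}
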