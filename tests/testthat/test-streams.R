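test_that("signal magnitude matches known norms and is symmetric", {
  expect_equal(signal_magnitude(1, 0, 0), 1)
  expect_equal(signal_magnitude(0.6, 0.8, 0), 1)
  expect_equal(signal_magnitude(2, 1, 2), 3)
  expect_error(signal_magnitude(NA, 0, 0), class = "bedwatch_domain_error")
  expect_error(signal_magnitude(Inf, 0, 0), class = "bedwatch_domain_error")

  set.seed(11)
  for (k in 1:20) {
    v <- rnorm(3)
    perm <- sample(3)
    signs <- sample(c(-1, 1), 3, replace = TRUE)
    w <- (v * signs)[perm]
    expect_equal(signal_magnitude(w[1], w[2], w[3]),
                 signal_magnitude(v[1], v[2], v[3]))
  }
})

test_that("stream validation enforces monotone time and finite values", {
  expect_error(imu_stream(t_ms = c(0, 20, 20), ax = 1),
               class = "bedwatch_validation_error")
  expect_error(imu_stream(t_ms = c(0, 20), ax = c(1, NaN)),
               class = "bedwatch_validation_error")
  expect_error(pressure_stream(0, -1, 0, 0), class = "bedwatch_validation_error")
  expect_error(pressure_stream(0, 2000, 0, 0), class = "bedwatch_validation_error")
  s <- imu_stream(t_ms = c(0, 20), ax = c(1, 1))
  expect_s3_class(s, "imu_stream")
  expect_equal(nrow(s), 2)
})

test_that("IMU CSV write/read round-trips simulated traces", {
  path <- withr::local_tempfile(fileext = ".csv")
  simple <- imu_stream(t_ms = c(0, 20), ax = c(1, 1))
  write_imu_csv(simple, path)
  back <- read_imu_csv(path)
  expect_equal(back$t_ms, c(0L, 20L))
  expect_equal(back$ax, c(1, 1))

  trace <- sim_fall_trace("left", seed = 5)
  write_imu_csv(trace, path)
  once <- read_imu_csv(path)
  expect_equal(once$t_ms, trace$t_ms)
  expect_equal(as.data.frame(once)[-1], as.data.frame(trace)[-1], tolerance = 1e-5)
  # a second write/read is the identity at the declared precision
  write_imu_csv(once, path)
  twice <- read_imu_csv(path)
  expect_identical(as.data.frame(twice), as.data.frame(once))
})

test_that("pressure CSV round-trips and malformed input is rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  ps <- sim_pressure_sequence("LYING_IN_MIDDLE", hold_ms = 2000, seed = 3)
  write_pressure_csv(ps, path)
  back <- read_pressure_csv(path)
  expect_equal(back$t_ms, ps$t_ms)
  expect_equal(back$middle, ps$middle, tolerance = 1e-5)

  writeLines(c("t_ms,left,middle,right", "0,1,2,3", "20,oops,2,3"), path)
  expect_error(read_pressure_csv(path), class = "bedwatch_parse_error")
  writeLines(c("wrong,header", "0,1"), path)
  expect_error(read_pressure_csv(path), class = "bedwatch_parse_error")
  writeLines(c("t_ms,left,middle,right", "0,1,2,3", "0,1,2,3"), path)
  expect_error(read_pressure_csv(path), class = "bedwatch_validation_error")
})

test_that("event constructor enforces kind-specific fields", {
  expect_error(event(0, "PRESENCE"), class = "bedwatch_validation_error")
  expect_error(event(0, "ALARM"), class = "bedwatch_validation_error")
  expect_error(event(0, "FALL_EVENT", position = "NO_PRESENCE"),
               class = "bedwatch_validation_error")
  ok <- event(5, "PRESENCE", position = "LYING_IN_MIDDLE", source = "bed")
  expect_equal(ok$position, "LYING_IN_MIDDLE")
})

test_that("event logs round-trip through JSON lines with absent keys omitted", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  log <- dplyr::bind_rows(
    event(100, "FALL_EVENT", source = "imu"),
    event(200, "PRESENCE", position = "NO_PRESENCE", source = "bed"),
    event(300, "ALARM", reason = "BED_EXIT")
  )
  write_events_jsonl(log, path)
  lines <- readLines(path)
  expect_false(grepl("position", lines[1]))
  expect_false(grepl("reason", lines[2]))
  back <- read_events_jsonl(path)
  expect_identical(as.data.frame(back), as.data.frame(log))
  write_events_jsonl(empty_events(), path)
  expect_equal(nrow(read_events_jsonl(path)), 0)
})

test_that("event bus preserves per-topic order and rejects unknown topics", {
  bus <- event_bus(c("fall", "movement"))
  e1 <- event(10, "FALL_EVENT")
  e2 <- event(20, "MOVEMENT_EVENT")
  bus_publish(bus, "fall", e1)
  got <- bus_collect(bus, "fall")
  expect_identical(as.data.frame(got), as.data.frame(e1))

  bus_publish(bus, "movement", e2)
  bus_publish(bus, "movement", event(30, "MOVEMENT_EVENT"))
  got <- bus_collect(bus, "movement")
  expect_equal(got$t_ms, c(20L, 30L))
  expect_equal(nrow(bus_collect(bus, "movement")), 0) # drained

  expect_error(bus_publish(bus, "nope", e1), class = "bedwatch_config_error")
  expect_error(bus_collect(bus, "nope"), class = "bedwatch_config_error")
})
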