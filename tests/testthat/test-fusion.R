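test_that("the risk rule alarms on empty bed and on sitting with movement only", {
  expect_equal(fuse_risk("NO_PRESENCE", FALSE), "BED_EXIT")
  expect_equal(fuse_risk("NO_PRESENCE", TRUE), "BED_EXIT")
  expect_equal(fuse_risk("SITTING_IN_RIGHT_EDGE", TRUE), "EXIT_INTENT")
  expect_equal(fuse_risk("SITTING_IN_LEFT_EDGE", TRUE), "EXIT_INTENT")
  expect_true(is.na(fuse_risk("SITTING_IN_RIGHT_EDGE", FALSE)))
  expect_true(is.na(fuse_risk("LYING_IN_MIDDLE", TRUE)))
  expect_true(is.na(fuse_risk("LYING_IN_LEFT_EDGE", TRUE)))
  expect_error(fuse_risk("NOT_RECOGNIZED", TRUE), class = "bedwatch_contract_error")
})

presence_at <- function(t, pos) event(t, "PRESENCE", position = pos, source = "bed")
movement_at <- function(t) event(t, "MOVEMENT_EVENT", source = "imu")

test_that("bed exit alarms once at the no-presence transition", {
  pres <- dplyr::bind_rows(presence_at(0, "LYING_IN_MIDDLE"),
                           presence_at(10000, "NO_PRESENCE"))
  al <- monitor_activity(pres, empty_events())
  expect_equal(nrow(al), 1)
  expect_equal(al$reason, "BED_EXIT")
  expect_equal(al$t_ms, 10000L)
})

test_that("exit intent requires movement within the recency window", {
  pres <- presence_at(5000, "SITTING_IN_RIGHT_EDGE")
  al <- monitor_activity(pres, movement_at(5800))
  expect_equal(nrow(al), 1)
  expect_equal(al$reason, "EXIT_INTENT")
  expect_equal(al$t_ms, 5800L)

  # late movement while still sitting alarms at the movement time
  al2 <- monitor_activity(pres, movement_at(9000))
  expect_equal(al2$t_ms, 9000L)
  expect_equal(al2$reason, "EXIT_INTENT")

  # movement after the position changed away from sitting does not alarm
  pres3 <- dplyr::bind_rows(presence_at(5000, "SITTING_IN_RIGHT_EDGE"),
                            presence_at(8000, "LYING_IN_MIDDLE"))
  expect_equal(nrow(monitor_activity(pres3, movement_at(9000))), 0)

  # movement preceding the sitting transition still counts if recent
  al4 <- monitor_activity(presence_at(5000, "SITTING_IN_LEFT_EDGE"),
                          movement_at(4500))
  expect_equal(al4$t_ms, 5000L)
  # ... but not when it is stale
  expect_equal(nrow(monitor_activity(presence_at(5000, "SITTING_IN_LEFT_EDGE"),
                                     movement_at(1000))), 0)
})

test_that("no alarm is ever produced while lying, and each episode alarms at most once", {
  pres <- dplyr::bind_rows(presence_at(0, "LYING_IN_MIDDLE"),
                           presence_at(20000, "LYING_IN_LEFT_EDGE"))
  movs <- dplyr::bind_rows(purrr::map(seq(1000, 30000, by = 2000), movement_at))
  expect_equal(nrow(monitor_activity(pres, movs)), 0)

  sitting <- presence_at(1000, "SITTING_IN_RIGHT_EDGE")
  al <- monitor_activity(sitting, movs)
  expect_equal(nrow(al), 1) # repeated movements do not repeat the alarm

  # re-armed after the position changes and sitting resumes
  back <- dplyr::bind_rows(
    presence_at(1000, "SITTING_IN_RIGHT_EDGE"),
    presence_at(10000, "LYING_IN_MIDDLE"),
    presence_at(20000, "SITTING_IN_RIGHT_EDGE")
  )
  al2 <- monitor_activity(back, movs)
  expect_equal(nrow(al2), 2)
  expect_true(all(al2$reason == "EXIT_INTENT"))
})

test_that("every no-presence episode yields exactly one bed-exit alarm", {
  set.seed(13)
  positions <- c("NO_PRESENCE", "LYING_IN_MIDDLE", "SITTING_IN_LEFT_EDGE",
                 "LYING_IN_RIGHT_EDGE")
  for (k in 1:20) {
    n <- sample(3:8, 1)
    labs <- positions[ceiling(runif(n) * 4)]
    labs <- labs[c(TRUE, labs[-1] != labs[-n])] # no consecutive duplicates
    pres <- dplyr::bind_rows(purrr::imap(labs, ~ presence_at(.y * 5000, .x)))
    movs <- dplyr::bind_rows(purrr::map(sample(1000:40000, 5), movement_at))
    al <- monitor_activity(pres, movs)
    expect_equal(sum(al$reason == "BED_EXIT"), sum(labs == "NO_PRESENCE"))
  }
})

test_that("adding a movement event never removes an alarm", {
  set.seed(29)
  pres <- dplyr::bind_rows(
    presence_at(2000, "SITTING_IN_LEFT_EDGE"),
    presence_at(12000, "LYING_IN_MIDDLE"),
    presence_at(22000, "NO_PRESENCE")
  )
  for (k in 1:20) {
    base_t <- sort(sample(seq(500, 30000, by = 500), 3))
    movs <- dplyr::bind_rows(purrr::map(base_t, movement_at))
    extra_t <- sample(seq(500, 30000, by = 500), 1)
    more <- dplyr::bind_rows(movs, movement_at(extra_t)) |> dplyr::arrange(t_ms)
    al_base <- monitor_activity(pres, movs)
    al_more <- monitor_activity(pres, more)
    expect_gte(nrow(al_more), nrow(al_base))
    expect_true(all(al_base$reason %in% al_more$reason))
  }
})
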