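test_that("a separable toy set is fit perfectly and reclassified to its own labels", {
  ds <- toy_dataset()
  model <- train_fall_classifier(ds)
  expect_equal(model$train_accuracy, 1)
  expect_equal(classify_windows(model, ds$window), ds$label)
  # quiescent 1 g-like window lands on the ADL side
  expect_equal(classify_windows(model, constant_window(ax = 0)), "ADL")
  expect_equal(classify_windows(model, constant_window(ax = 1.05)), "ADL")
})

test_that("training requires both classes and valid labels", {
  ds <- toy_dataset()
  expect_error(train_fall_classifier(ds[ds$label == "FALL", ]),
               class = "bedwatch_validation_error")
  bad <- ds; bad$label[1] <- "OOPS"
  expect_error(train_fall_classifier(bad), class = "bedwatch_validation_error")
})

test_that("training is deterministic and the model serializes bit-stably", {
  ds <- toy_dataset()
  m1 <- train_fall_classifier(ds)
  m2 <- train_fall_classifier(ds)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_fall_model(m1, p1)
  write_fall_model(m2, p2)
  expect_identical(readLines(p1), readLines(p2))

  back <- read_fall_model(p1)
  p3 <- withr::local_tempfile(fileext = ".json")
  write_fall_model(back, p3)
  expect_identical(readLines(p3), readLines(p1))
  expect_equal(classify_windows(back, ds$window), ds$label)
  expect_equal(back$stats, m1$stats)
})

test_that("the stored decision function reproduces the fitting library's predictions", {
  set.seed(31)
  ds <- sim_dataset(n_reps = 4, seed = 17)
  for (kern in c("linear", "radial")) {
    model <- train_fall_classifier(ds, kernel = kern)
    feats <- dplyr::bind_rows(purrr::map(ds$window, extract_features))
    x <- as.matrix(normalize_features(feats, model$stats))
    y <- factor(ds$label, levels = c("FALL", "ADL"))
    refit <- e1071::svm(x, y, kernel = kern, cost = 1, scale = FALSE)
    expect_equal(classify_windows(model, ds$window),
                 as.character(predict(refit, x)))
  }
})

test_that("classification is invariant to duplicating every sample in the window", {
  ds <- toy_dataset()
  model <- train_fall_classifier(ds)
  w <- ds$window[[1]]
  dup <- imu_stream(
    t_ms = seq(0L, by = 10L, length.out = 2 * nrow(w)),
    ax = rep(w$ax, each = 2), ay = rep(w$ay, each = 2), az = rep(w$az, each = 2),
    gx = rep(w$gx, each = 2), gy = rep(w$gy, each = 2), gz = rep(w$gz, each = 2)
  )
  expect_equal(classify_windows(model, dup, rate_hz = 100),
               classify_windows(model, w))
})

test_that("gateway processing raises fall alarms only for fall-classified windows", {
  ds <- toy_dataset()
  model <- train_fall_classifier(ds)
  fall_ev <- event(1000, "FALL_EVENT", source = "imu")
  attr(fall_ev, "window") <- NULL
  fall_ev$window <- list(constant_window(ax = 3))
  adl_ev <- event(2000, "FALL_EVENT", source = "imu")
  adl_ev$window <- list(constant_window(ax = 1))
  both <- dplyr::bind_rows(fall_ev, adl_ev)

  alarms <- process_fall_events(both, model)
  expect_equal(nrow(alarms), 1)
  expect_equal(alarms$reason, "FALL")
  expect_equal(alarms$t_ms, 1000L)
  decisions <- attr(alarms, "decisions")
  expect_equal(decisions$predicted, c("FALL", "ADL"))

  none <- process_fall_events(empty_events(), model)
  expect_equal(nrow(none), 0)

  bad <- fall_ev; bad$window <- list(imu_stream(integer(), double()))
  expect_error(process_fall_events(bad, model), class = "bedwatch_validation_error")
})

test_that("tidy and glance expose normalization statistics and fit summary", {
  ds <- toy_dataset()
  model <- train_fall_classifier(ds)
  td <- generics::tidy(model)
  expect_equal(nrow(td), 13)
  expect_true(all(c("feature", "mean", "sd", "weight") %in% names(td)))
  # svm_mean separates the classes, so it must carry positive fall weight
  expect_gt(td$weight[td$feature == "svm_mean"], 0)
  gl <- generics::glance(model)
  expect_equal(gl$n_train, 8)
  expect_equal(gl$train_accuracy, 1)
  expect_equal(gl$kernel, "linear")
})

test_that("on the simulated protocol the classifier beats chance and confuses backward falls most", {
  train_ds <- sim_dataset(n_reps = 8, seed = 2)
  test_ds <- sim_dataset(n_reps = 5, seed = 901)
  model <- train_fall_classifier(train_ds)
  pred <- classify_windows(model, test_ds$window)
  acc <- mean(pred == test_ds$label)
  expect_gt(acc, 0.7)

  fall_types <- c("forward", "backward", "left", "right")
  miss <- purrr::map_dbl(fall_types, function(ft) {
    idx <- test_ds$activity == ft
    sum(pred[idx] != "FALL")
  })
  names(miss) <- fall_types
  expect_gte(miss[["backward"]], max(miss[c("forward", "left", "right")]))
})
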