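test_that("binary metrics reproduce the published headline numbers from the counts", {
  counts <- fall_test_counts()
  expect_equal(sum(counts$tp), 81)
  expect_equal(sum(counts$tn), 63)
  expect_equal(sum(counts$fp), 3)
  expect_equal(sum(counts$fn), 7)
  m <- binary_metrics(counts)
  expect_equal(m$accuracy, 93.51, tolerance = 0.01)
  expect_equal(m$sensitivity, 92.04, tolerance = 0.01)
  expect_equal(m$specificity, 95.45, tolerance = 0.01)
})

test_that("binary metrics handle degenerate counts explicitly", {
  expect_equal(unlist(binary_metrics(tibble::tibble(tp = 1, tn = 1, fp = 0, fn = 0))),
               c(accuracy = 100, sensitivity = 100, specificity = 100))
  m <- binary_metrics(tibble::tibble(tp = 0, tn = 10, fp = 0, fn = 10))
  expect_equal(m$accuracy, 50)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 100)
  expect_error(binary_metrics(tibble::tibble(tp = 0, tn = 5, fp = 1, fn = 0)),
               class = "bedwatch_metric_error") # no positives
  expect_error(binary_metrics(tibble::tibble(tp = 5, tn = 0, fp = 0, fn = 1)),
               class = "bedwatch_metric_error") # no negatives
})

test_that("one-vs-rest metrics on the published position matrix match its table", {
  m <- bed_position_confusion()
  pc <- per_class_metrics(m)
  get <- function(cls, col) pc[[col]][pc$class == cls]
  expect_equal(get("SITTING_IN_LEFT_EDGE", "sensitivity"), 100 * 6 / 11,
               tolerance = 1e-10)
  expect_equal(round_half_up(get("SITTING_IN_LEFT_EDGE", "sensitivity")), 54.55)
  expect_equal(get("LYING_IN_LEFT_EDGE", "specificity"), 100 * 50 / 55,
               tolerance = 1e-10)
  expect_equal(get("NO_PRESENCE", "accuracy"), 100)
  expect_equal(get("macro", "accuracy"), 96.97, tolerance = 0.01)
  expect_equal(get("macro", "sensitivity"), 90.91, tolerance = 0.01)
  expect_equal(get("macro", "specificity"), 98.18, tolerance = 0.01)

  ident <- diag(5); rownames(ident) <- colnames(ident) <- letters[1:5]
  pci <- per_class_metrics(ident)
  expect_true(all(pci$accuracy == 100))
  expect_true(all(pci$sensitivity == 100))

  # macro metrics are invariant under class reordering
  ord <- c(3, 1, 6, 2, 5, 4)
  pc2 <- per_class_metrics(m[ord, ord])
  expect_equal(pc2$accuracy[pc2$class == "macro"], get("macro", "accuracy"))
  expect_equal(pc2$sensitivity[pc2$class == "macro"], get("macro", "sensitivity"))
})

test_that("prevalence-weighted accuracy matches its closed form and the counts identity", {
  expect_equal(prevalence_accuracy(0.925, 1.0, 0.5), 96.25)
  expect_equal(prevalence_accuracy(0.7, 0.9, 1), 70)
  expect_equal(prevalence_accuracy(0.7, 0.9, 0), 90)
  expect_error(prevalence_accuracy(1.2, 0.5, 0.5), class = "bedwatch_validation_error")

  set.seed(17)
  for (k in 1:25) {
    cts <- tibble::tibble(tp = sample(1:50, 1), tn = sample(1:50, 1),
                          fp = sample(0:20, 1), fn = sample(0:20, 1))
    m <- binary_metrics(cts)
    prev <- (cts$tp + cts$fn) / sum(cts)
    expect_equal(m$accuracy,
                 prevalence_accuracy(m$sensitivity / 100, m$specificity / 100, prev))
  }
})

test_that("independent-stage combination multiplies metric fractions", {
  expect_equal(combine_independent(0.9250, 0.7727), 71.47475, tolerance = 1e-10)
  expect_equal(combine_independent(0.63, 1.0), 63)
  expect_equal(combine_independent(1.0, 1.0), 100)
  expect_error(combine_independent(1.4, 0.5), class = "bedwatch_validation_error")
})

test_that("trial tabulation reconstructs confusion structures", {
  truth <- tibble::tibble(trial = 1:6, actual = c("a", "a", "b", "b", "c", "c"))
  perfect <- tibble::tibble(trial = 1:6, predicted = truth$actual)
  m <- evaluate_trials(perfect, truth)
  expect_true(all(m[upper.tri(m) | lower.tri(m)] == 0))
  expect_equal(diag(m), c(a = 2, b = 2, c = 2))

  swapped <- perfect
  swapped$predicted[c(1, 3)] <- c("b", "a")
  m2 <- evaluate_trials(swapped, truth)
  expect_equal(sum(m != m2), 4) # two off-diagonal gains, two diagonal losses

  bin <- evaluate_trials(
    tibble::tibble(trial = 1:4, predicted = c("FALL", "FALL", "ADL", "ADL")),
    tibble::tibble(trial = 1:4, actual = c("FALL", "ADL", "FALL", "ADL")),
    positive = "FALL"
  )
  expect_equal(unlist(bin), c(tp = 1, tn = 1, fp = 1, fn = 1))

  expect_error(
    evaluate_trials(tibble::tibble(trial = 1:2, predicted = "a"),
                    tibble::tibble(trial = 2:3, actual = "a")),
    class = "bedwatch_validation_error"
  )
})

test_that("the published position matrix can be rebuilt from its 66 labelled trials", {
  m <- bed_position_confusion()
  classes <- rownames(m)
  rows <- list()
  trial <- 0
  for (actual in classes) {
    for (pred in classes) {
      k <- m[pred, actual]
      if (k > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          trial = trial + seq_len(k), predicted = pred, actual = actual
        )
        trial <- trial + k
      }
    }
  }
  trials <- dplyr::bind_rows(rows)
  expect_equal(nrow(trials), 66)
  rebuilt <- evaluate_trials(trials[c("trial", "predicted")],
                             trials[c("trial", "actual")], classes = classes)
  expect_identical(unname(rebuilt), unname(m))
})

test_that("the packaged tables reproduce the published combination arithmetic", {
  tabs <- reproduce_tables()
  expect_equal(tabs$motion_phases$accuracy[1], 96.25)
  ei <- tabs$exit_intent
  expect_equal(ei$sitting_stage[ei$metric == "accuracy"], 96.21, tolerance = 0.01)
  expect_equal(ei$sitting_stage[ei$metric == "sensitivity"], 77.27, tolerance = 0.01)
  expect_equal(ei$combined[ei$metric == "sensitivity"], 71.47, tolerance = 0.01)
  expect_equal(ei$combined[ei$metric == "specificity"], 100)
})
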