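#' Binary classification metrics from confusion counts
#'
#' Accuracy, sensitivity (true-positive rate) and specificity (true-negative
#' rate) in percent: `accuracy = 100 (TP+TN)/(TP+TN+FP+FN)`,
#' `sensitivity = 100 TP/(TP+FN)`, `specificity = 100 TN/(TN+FP)`. A metric
#' whose denominator is zero is an error rather than a silent zero, since
#' silent zeros would corrupt macro averages.
#'
#' @param counts A data frame (or one-row tibble) with columns `tp`, `tn`,
#'   `fp`, `fn`; multiple rows are summed before computing.
#' @return A one-row tibble: `accuracy`, `sensitivity`, `specificity`
#'   (percent).
#' @examples
#' binary_metrics(tibble::tibble(tp = 81, tn = 63, fp = 3, fn = 7))
#' @export
binary_metrics <- function(counts) {
  stopifnot(all(c("tp", "tn", "fp", "fn") %in% names(counts)))
  tp <- sum(counts$tp); tn <- sum(counts$tn)
  fp <- sum(counts$fp); fn <- sum(counts$fn)
  if (any(c(tp, tn, fp, fn) < 0)) {
    abort("confusion counts must be non-negative", class = "bedwatch_validation_error")
  }
  total <- tp + tn + fp + fn
  if (total == 0) abort("accuracy undefined: no trials", class = "bedwatch_metric_error")
  if (tp + fn == 0) abort("sensitivity undefined: no positives", class = "bedwatch_metric_error")
  if (tn + fp == 0) abort("specificity undefined: no negatives", class = "bedwatch_metric_error")
  tibble(
    accuracy = 100 * (tp + tn) / total,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp)
  )
}

#' Per-class and macro metrics for a multi-class confusion matrix
#'
#' Reduces the matrix one-vs-rest per class to binary counts
#' (`tp` = diagonal, `fn` = rest of the column, `fp` = rest of the row,
#' `tn` = remainder), computes [binary_metrics()] per class, and appends the
#' macro (arithmetic) mean across classes as class `"macro"`.
#'
#' @param m A square numeric matrix, entry `[predicted, actual]`, with
#'   matching row/column names (or none).
#' @return A tibble with columns `class`, `tp`, `tn`, `fp`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`; the last row is the macro
#'   mean (counts `NA`).
#' @export
per_class_metrics <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) {
    abort("confusion matrix must be square", class = "bedwatch_validation_error")
  }
  classes <- rownames(m) %||% paste0("class", seq_len(nrow(m)))
  total <- sum(m)
  rows <- map(seq_len(nrow(m)), function(k) {
    tp <- m[k, k]
    fn <- sum(m[, k]) - tp
    fp <- sum(m[k, ]) - tp
    tn <- total - tp - fn - fp
    if (tp + fn == 0) {
      abort(sprintf("empty class: %s", classes[k]), class = "bedwatch_metric_error")
    }
    cbind(tibble(class = classes[k], tp = tp, tn = tn, fp = fp, fn = fn),
          binary_metrics(tibble(tp = tp, tn = tn, fp = fp, fn = fn)))
  })
  out <- bind_rows(rows)
  macro <- tibble(
    class = "macro", tp = NA_real_, tn = NA_real_, fp = NA_real_, fn = NA_real_,
    accuracy = mean(out$accuracy),
    sensitivity = mean(out$sensitivity),
    specificity = mean(out$specificity)
  )
  bind_rows(out, macro)
}

#' Prevalence-weighted accuracy
#'
#' Accuracy decomposed into sensitivity and specificity weighted by class
#' prevalence: `100 (sens * prev + spec * (1 - prev))`. With counts, this is
#' an algebraic identity with `(TP+TN)/total`.
#'
#' @param sensitivity,specificity,prevalence Fractions in `[0, 1]`.
#' @return Accuracy in percent.
#' @examples
#' prevalence_accuracy(0.925, 1.0, 0.5) # 96.25
#' @export
prevalence_accuracy <- function(sensitivity, specificity, prevalence) {
  vals <- c(sensitivity, specificity, prevalence)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    abort("inputs must be fractions in [0, 1]", class = "bedwatch_validation_error")
  }
  100 * (sensitivity * prevalence + specificity * (1 - prevalence))
}

#' Combine the metrics of two independent detection stages
#'
#' When an alarm requires both of two independent stages to succeed, the
#' combined probability per metric is the product of the stage
#' probabilities (`P(A and B) = P(A) P(B)`). Elementwise over equal-length
#' vectors of fractions; returns percent.
#'
#' @param stage_a,stage_b Numeric fractions in `[0, 1]` (scalars or
#'   equal-length vectors).
#' @return `100 * stage_a * stage_b`.
#' @examples
#' combine_independent(0.9250, 0.7727) # 71.47...
#' @export
combine_independent <- function(stage_a, stage_b) {
  vals <- c(stage_a, stage_b)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    abort("stage metrics must be fractions in [0, 1]", class = "bedwatch_validation_error")
  }
  100 * stage_a * stage_b
}

#' Tabulate predictions against ground truth
#'
#' Joins predictions and truth on `trial` and tabulates. With two classes
#' and a designated positive class, returns binary counts; otherwise
#' returns the full confusion matrix, entry `[predicted, actual]`.
#'
#' @param predictions Tibble with columns `trial`, `predicted`.
#' @param truth Tibble with columns `trial`, `actual`.
#' @param positive Optional positive-class label; when supplied, the result
#'   is a one-row tibble of `tp`, `tn`, `fp`, `fn`.
#' @param classes Optional class ordering for the matrix.
#' @return A counts tibble or a confusion matrix.
#' @export
evaluate_trials <- function(predictions, truth, positive = NULL, classes = NULL) {
  stopifnot(all(c("trial", "predicted") %in% names(predictions)),
            all(c("trial", "actual") %in% names(truth)))
  joined <- dplyr::inner_join(predictions, truth, by = "trial")
  if (nrow(joined) != nrow(predictions) || nrow(joined) != nrow(truth)) {
    abort("unmatched trial identifiers between predictions and truth",
          class = "bedwatch_validation_error")
  }
  if (!is.null(positive)) {
    pos_pred <- joined$predicted == positive
    pos_act <- joined$actual == positive
    return(tibble(
      tp = sum(pos_pred & pos_act), tn = sum(!pos_pred & !pos_act),
      fp = sum(pos_pred & !pos_act), fn = sum(!pos_pred & pos_act)
    ))
  }
  classes <- classes %||% sort(unique(c(joined$predicted, joined$actual)))
  m <- table(factor(joined$predicted, levels = classes),
             factor(joined$actual, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(predicted = classes, actual = classes))
  m
}

#' Round half up to a number of decimals
#'
#' Report tables round half up (2.5 -> 3), unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimals (default 2).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# ---- Packaged fixtures of the published validation counts ------------------

#' Published per-activity fall-detection test counts
#'
#' The per-activity outcome counts of the fall-detection validation battery
#' (11 subjects, 7 exercises, 2 repetitions each): falls contribute true
#' positives and false negatives, ADLs true negatives and false positives.
#' Shipped as a plain-text fixture and used to reproduce the headline
#' accuracy/sensitivity/specificity.
#'
#' @return A tibble with columns `activity`, `label`, `tp`, `tn`, `fp`, `fn`.
#' @export
fall_test_counts <- function() {
  path <- system.file("extdata", "fall_test_counts.csv", package = "bedwatch",
                      mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Published bed-position confusion matrix
#'
#' The 6-position confusion matrix of the bed-presence validation battery
#' (11 subjects performing exit bed, sitting right, lying middle, lying
#' right, lying left, sitting left), entry `[predicted, actual]`.
#'
#' @return A 6x6 integer matrix with position dimnames.
#' @export
bed_position_confusion <- function() {
  path <- system.file("extdata", "bed_position_confusion.csv",
                      package = "bedwatch", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- c("predicted", "actual")
  m
}

#' Published movement-detector phase metrics
#'
#' Sensitivity/specificity (fractions) of the threshold movement detector
#' per bed-exit phase in the published validation: 40 exit trials split
#' across phases plus 40 controlled negative (rolling) trials.
#'
#' @return A tibble with columns `phase`, `sensitivity`, `specificity`,
#'   `prevalence`.
#' @export
motion_phase_metrics <- function() {
  tibble(
    phase = c("lying-sitting", "sitting-standing", "standing-walking"),
    sensitivity = c(0.925, 1.0, 1.0),
    specificity = c(1.0, 1.0, 1.0),
    prevalence = c(0.5, 0.5, 0.5)
  )
}

#' Reproduce the published evaluation tables from the packaged fixtures
#'
#' Recomputes, from the shipped counts: the headline fall-detection metrics;
#' the per-class and macro bed-position metrics; the prevalence-weighted
#' movement-detector accuracies per phase; and the combined
#' intention-to-exit metrics (mean sitting-position metrics from the
#' position table, multiplied by the lying-sitting movement metrics as
#' independent stages).
#'
#' @return A named list of tibbles: `fall_detection`, `bed_position`,
#'   `motion_phases`, `exit_intent`.
#' @export
reproduce_tables <- function() {
  fall <- binary_metrics(fall_test_counts())

  pos <- per_class_metrics(bed_position_confusion())

  motion <- motion_phase_metrics()
  motion$accuracy <- prevalence_accuracy(motion$sensitivity, motion$specificity,
                                         motion$prevalence)

  sitting <- pos[pos$class %in% c("SITTING_IN_RIGHT_EDGE", "SITTING_IN_LEFT_EDGE"), ]
  lying_sitting <- motion[motion$phase == "lying-sitting", ]
  # both stages in percent; the combination multiplies the stage fractions
  # at report precision (2 decimals), mirroring the published arithmetic
  sitting_stage <- c(accuracy = mean(sitting$accuracy),
                     sensitivity = mean(sitting$sensitivity),
                     specificity = mean(sitting$specificity))
  motion_stage <- c(accuracy = lying_sitting$accuracy,
                    sensitivity = 100 * lying_sitting$sensitivity,
                    specificity = 100 * lying_sitting$specificity)
  exit_intent <- tibble(
    metric = names(sitting_stage),
    sitting_stage = unname(sitting_stage),
    motion_stage = unname(motion_stage),
    combined = combine_independent(round_half_up(sitting_stage, 2) / 100,
                                   round_half_up(motion_stage, 2) / 100)
  )

  list(fall_detection = fall, bed_position = pos, motion_phases = motion,
       exit_intent = exit_intent)
}
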