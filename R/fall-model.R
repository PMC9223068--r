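#' Train the fall / ADL classifier
#'
#' Fits a maximum-margin (support-vector) binary classifier distinguishing
#' fall windows from activities of daily living (ADLs). Features are
#' extracted from each labelled window, standardised with statistics
#' computed on the training set only, and the classifier is fitted on the
#' standardised features. The fitted object stores everything needed for
#' later prediction — kernel, support vectors, dual coefficients, intercept
#' and normalization statistics — and serializes losslessly to JSON.
#'
#' @param dataset Tibble with a list-column `window` of `imu_stream` windows
#'   and a character column `label` in `{"FALL", "ADL"}`; an optional
#'   `activity` column is carried through for confusion analysis.
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param cost Soft-margin regularization constant (default 1).
#' @param rate_hz Sampling rate of the windows (default 50).
#' @param fall_threshold_g Threshold used by the fall-time feature.
#' @return A `fall_model` object.
#' @seealso [classify_windows()], [write_fall_model()], [tidy.fall_model()]
#' @export
train_fall_classifier <- function(dataset, kernel = c("linear", "radial"),
                                  cost = 1, rate_hz = 50,
                                  fall_threshold_g = 2.5) {
  kernel <- match.arg(kernel)
  if (!all(c("window", "label") %in% names(dataset))) {
    abort("dataset needs `window` and `label` columns", class = "bedwatch_validation_error")
  }
  labels <- as.character(dataset$label)
  if (!all(labels %in% c("FALL", "ADL"))) {
    abort("labels must be FALL or ADL", class = "bedwatch_validation_error")
  }
  if (length(unique(labels)) < 2) {
    abort("training set must contain both FALL and ADL windows",
          class = "bedwatch_validation_error")
  }

  feats <- bind_rows(map(dataset$window, extract_features,
                         rate_hz = rate_hz, fall_threshold_g = fall_threshold_g))
  stats <- tibble(
    feature = FEATURE_NAMES,
    mean = map_dbl(FEATURE_NAMES, ~ mean(feats[[.x]])),
    sd = map_dbl(FEATURE_NAMES, ~ pop_sd(feats[[.x]]))
  )
  x <- as.matrix(normalize_features(feats, stats))
  y <- factor(labels, levels = c("FALL", "ADL"))

  fit <- e1071::svm(x, y, kernel = kernel, cost = cost, scale = FALSE)
  gamma <- if (kernel == "radial") fit$gamma else NA_real_

  model <- structure(
    list(
      kernel = kernel,
      cost = cost,
      gamma = gamma,
      support_vectors = unname(as.matrix(fit$SV)),
      dual_coefs = as.double(fit$coefs),
      rho = as.double(fit$rho),
      orientation = 1,
      classes = c("FALL", "ADL"),
      stats = stats,
      n_train = nrow(x),
      format_version = 1L
    ),
    class = "fall_model"
  )

  # libsvm's decision-value sign follows its internal label order; anchor
  # our decision function to the library's own predictions on the training
  # data so the serialized parameters are self-contained.
  own <- decision_values(model, x)
  lib <- as.character(predict(fit, x))
  agree <- mean((own > 0) == (lib == "FALL"))
  if (agree < 0.5) model$orientation <- -1

  pred <- predict_from_matrix(model, x)
  model$train_accuracy <- mean(pred == labels)
  model
}

kernel_matrix <- function(model, x) {
  sv <- model$support_vectors
  if (model$kernel == "linear") {
    x %*% t(sv)
  } else {
    d2 <- outer(rowSums(x^2), rowSums(sv^2), "+") - 2 * x %*% t(sv)
    exp(-model$gamma * pmax(d2, 0))
  }
}

decision_values <- function(model, x) {
  as.double(kernel_matrix(model, x) %*% model$dual_coefs - model$rho)
}

predict_from_matrix <- function(model, x) {
  dec <- model$orientation * decision_values(model, x)
  ifelse(dec > 0, model$classes[1], model$classes[2])
}

#' Classify captured windows as falls or ADLs
#'
#' Runs the full gateway-side pipeline on each window: feature extraction,
#' standardisation with the model's training statistics, and the
#' support-vector decision. Deterministic.
#'
#' @param model A trained `fall_model`.
#' @param windows A list of `imu_stream` windows, or a single window.
#' @param rate_hz Sampling rate of the windows.
#' @return Character vector of `"FALL"` / `"ADL"`, one per window.
#' @export
classify_windows <- function(model, windows, rate_hz = 50) {
  if (!inherits(model, "fall_model")) {
    abort("model must be a trained fall_model", class = "bedwatch_validation_error")
  }
  if (is.data.frame(windows)) windows <- list(windows)
  feats <- bind_rows(map(windows, extract_features, rate_hz = rate_hz))
  x <- as.matrix(normalize_features(feats, model$stats))
  predict_from_matrix(model, x)
}

#' Turn classified fall events into caregiver alarms
#'
#' The gateway's decision step: each `FALL_EVENT` window is classified, and
#' an `ALARM` with reason `FALL` is raised for every window classified as a
#' fall. The per-event decisions are attached to the returned log as
#' attribute `"decisions"`.
#'
#' @param fall_events Event tibble from [detect_falls()] (must carry the
#'   `window` list-column with non-empty windows).
#' @param model A trained `fall_model`.
#' @param rate_hz Sampling rate of the windows.
#' @return An event tibble of `ALARM(reason = "FALL")` rows (possibly empty),
#'   with attribute `"decisions"`: a tibble of `t_ms`, `predicted`.
#' @export
process_fall_events <- function(fall_events, model, rate_hz = 50) {
  if (nrow(fall_events) == 0) {
    out <- empty_events()
    attr(out, "decisions") <- tibble(t_ms = integer(), predicted = character())
    return(out)
  }
  if (is.null(fall_events$window) ||
      any(map_dbl(fall_events$window, nrow) == 0)) {
    abort("fall events must carry non-empty windows", class = "bedwatch_validation_error")
  }
  predicted <- classify_windows(model, fall_events$window, rate_hz = rate_hz)
  alarms <- fall_events[predicted == "FALL", c("t_ms", "kind", "position", "reason", "source")]
  out <- if (nrow(alarms) > 0) {
    bind_rows(map(alarms$t_ms, ~ event(.x, "ALARM", reason = "FALL", source = "imu")))
  } else {
    empty_events()
  }
  attr(out, "decisions") <- tibble(t_ms = fall_events$t_ms, predicted = predicted)
  out
}

# ---- Serialization ---------------------------------------------------------

#' Save and load a trained fall model as JSON
#'
#' The model file is a versioned JSON container holding the kernel name and
#' hyperparameters, support vectors, dual coefficients, intercept,
#' normalization statistics and class labels. Numbers are written at full
#' precision, so a save/load round trip reproduces the model bit for bit.
#'
#' @param model A `fall_model`.
#' @param path File path.
#' @return `write_fall_model()` returns `path` invisibly;
#'   `read_fall_model()` returns the reconstructed `fall_model`.
#' @export
write_fall_model <- function(model, path) {
  stopifnot(inherits(model, "fall_model"))
  payload <- list(
    format_version = model$format_version,
    kernel = model$kernel,
    cost = model$cost,
    gamma = model$gamma,
    rho = model$rho,
    orientation = model$orientation,
    classes = model$classes,
    n_train = model$n_train,
    train_accuracy = model$train_accuracy,
    dual_coefs = model$dual_coefs,
    support_vectors = model$support_vectors,
    stats = model$stats
  )
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE, na = "null")
  writeLines(json, path, sep = "\n")
  invisible(path)
}

#' @rdname write_fall_model
#' @export
read_fall_model <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("model file not found: %s", path), class = "bedwatch_io_error")
  }
  p <- jsonlite::fromJSON(readLines(path, encoding = "UTF-8"))
  structure(
    list(
      kernel = p$kernel,
      cost = p$cost,
      gamma = if (is.null(p$gamma)) NA_real_ else p$gamma,
      support_vectors = matrix(as.double(p$support_vectors),
                               nrow = nrow(p$support_vectors)),
      dual_coefs = as.double(p$dual_coefs),
      rho = as.double(p$rho),
      orientation = p$orientation,
      classes = as.character(p$classes),
      stats = as_tibble(p$stats),
      n_train = p$n_train,
      train_accuracy = p$train_accuracy,
      format_version = p$format_version
    ),
    class = "fall_model"
  )
}

#' @export
print.fall_model <- function(x, ...) {
  cat("<fall_model>\n")
  cat("  kernel:", x$kernel, " cost:", x$cost, "\n")
  cat("  support vectors:", nrow(x$support_vectors), "of", x$n_train, "windows\n")
  cat("  training accuracy:", sprintf("%.1f%%", 100 * x$train_accuracy), "\n")
  invisible(x)
}

# ---- broom-style accessors -------------------------------------------------

#' Tidy a fitted fall model
#'
#' One row per feature with its training mean and standard deviation and,
#' for the linear kernel, the primal weight of the separating hyperplane in
#' standardised feature space (positive weights push toward the FALL class).
#'
#' @param x A `fall_model`.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `mean`, `sd` and (linear kernel)
#'   `weight`.
#' @export
tidy.fall_model <- function(x, ...) {
  out <- x$stats
  if (x$kernel == "linear") {
    w <- x$orientation * as.double(t(x$support_vectors) %*% x$dual_coefs)
    out$weight <- w
  }
  out
}

#' Glance at a fitted fall model
#'
#' @param x A `fall_model`.
#' @param ... Unused.
#' @return A one-row tibble: `kernel`, `cost`, `n_train`, `n_support`,
#'   `train_accuracy`.
#' @export
glance.fall_model <- function(x, ...) {
  tibble(
    kernel = x$kernel, cost = x$cost, n_train = x$n_train,
    n_support = nrow(x$support_vectors),
    train_accuracy = x$train_accuracy
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
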