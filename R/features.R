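FEATURE_NAMES <- c(
  "svm_mean", "svm_var", "acc_y_mean", "acc_z_mean",
  "gyr_y_mean", "gyr_z_mean", "fall_time_ms",
  "acc_y_std", "acc_z_std", "gyr_y_std", "gyr_z_std",
  "fourier_acc_svm", "fourier_gyr_svm"
)

# Population variance/std: captured windows are complete signals, not draws
# from a larger population.
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

# Largest non-DC DFT magnitude of the mean-removed series, normalized so a
# sinusoid of amplitude A (with an integer number of periods in the window)
# yields A. A constant series yields 0.
dominant_fourier <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  spec <- Mod(fft(x - mean(x))) * 2 / n
  max(spec[-1])
}

#' Extract the 13 movement features from a captured window
#'
#' Summarises a captured IMU window into the feature vector the fall/ADL
#' classifier consumes: mean and variance of the acceleration signal vector
#' magnitude; means and population standard deviations of the y and z
#' acceleration (g) and angular velocity (deg/s) components; the fall time;
#' and the dominant Fourier coefficient of the acceleration and angular
#' velocity magnitude series. The x-axis statistics are intentionally
#' absent: with the sensor worn at the waist, x carries mostly the static
#' gravity component while y/z capture the orientation change of a fall.
#'
#' Fall time is the span (ms) from the first sample of the window (the
#' triggering peak) to the last sample whose signal magnitude still exceeds
#' `fall_threshold_g` — the duration of the impact inside the window; 0 when
#' only the peak itself exceeds the threshold. The Fourier features are the
#' largest non-DC magnitude of the discrete Fourier transform of the
#' mean-removed magnitude series, scaled by 2/N so a pure sinusoid of
#' amplitude A yields A.
#'
#' @param window Non-empty `imu_stream` tibble with approximately uniform
#'   sample spacing (within 10% of `1/rate_hz`).
#' @param rate_hz Sampling rate used to check spacing (default 50).
#' @param fall_threshold_g Threshold used in the fall-time feature
#'   (default 2.5 g, the state-machine trigger).
#' @return A one-row tibble with the 13 feature columns.
#' @examples
#' w <- imu_stream(t_ms = seq(0, 980, by = 20), ax = 1)
#' extract_features(w)
#' @export
extract_features <- function(window, rate_hz = 50, fall_threshold_g = 2.5) {
  window <- validate_imu_stream(window)
  if (nrow(window) == 0) {
    abort("cannot extract features from an empty window",
          class = "bedwatch_domain_error")
  }
  if (nrow(window) > 1) {
    spacing <- diff(window$t_ms)
    nominal <- 1000 / rate_hz
    if (any(abs(spacing - nominal) > 0.1 * nominal)) {
      abort("window spacing deviates more than 10% from the nominal rate",
            class = "bedwatch_domain_error")
    }
  }
  acc_svm <- signal_magnitude(window$ax, window$ay, window$az)
  gyr_svm <- signal_magnitude(window$gx, window$gy, window$gz)
  over <- which(acc_svm > fall_threshold_g)
  fall_time <- if (length(over) > 1) {
    window$t_ms[max(over)] - window$t_ms[1]
  } else 0

  tibble(
    svm_mean = mean(acc_svm),
    svm_var = pop_var(acc_svm),
    acc_y_mean = mean(window$ay),
    acc_z_mean = mean(window$az),
    gyr_y_mean = mean(window$gy),
    gyr_z_mean = mean(window$gz),
    fall_time_ms = as.double(fall_time),
    acc_y_std = pop_sd(window$ay),
    acc_z_std = pop_sd(window$az),
    gyr_y_std = pop_sd(window$gy),
    gyr_z_std = pop_sd(window$gz),
    fourier_acc_svm = dominant_fourier(acc_svm),
    fourier_gyr_svm = dominant_fourier(gyr_svm)
  )
}

#' Standardise feature vectors with training statistics
#'
#' Z-scores each feature using the per-feature mean and standard deviation
#' learned on the training set. Features with zero training variance are
#' mapped to 0 rather than dividing by zero (they carry no information for
#' the margin).
#'
#' @param features Tibble of feature rows (13 columns, as from
#'   [extract_features()]).
#' @param stats Tibble with columns `feature`, `mean`, `sd` covering all 13
#'   features (as stored in a trained model).
#' @return Tibble of the same shape with standardised values.
#' @export
normalize_features <- function(features, stats) {
  if (!all(FEATURE_NAMES %in% names(features)) ||
      !setequal(stats$feature, FEATURE_NAMES)) {
    abort("feature/statistics dimension mismatch", class = "bedwatch_validation_error")
  }
  mu <- stats$mean[match(FEATURE_NAMES, stats$feature)]
  sg <- stats$sd[match(FEATURE_NAMES, stats$feature)]
  out <- features[FEATURE_NAMES]
  for (j in seq_along(FEATURE_NAMES)) {
    out[[j]] <- if (sg[j] > 0) (out[[j]] - mu[j]) / sg[j] else rep(0, nrow(out))
  }
  out
}

#' @rdname normalize_features
#' @description `denormalize_features()` inverts the z-scoring (zero-variance
#'   features are restored to their training mean).
#' @export
denormalize_features <- function(features, stats) {
  mu <- stats$mean[match(FEATURE_NAMES, stats$feature)]
  sg <- stats$sd[match(FEATURE_NAMES, stats$feature)]
  out <- features[FEATURE_NAMES]
  for (j in seq_along(FEATURE_NAMES)) {
    out[[j]] <- if (sg[j] > 0) out[[j]] * sg[j] + mu[j] else rep(mu[j], nrow(out))
  }
  out
}
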