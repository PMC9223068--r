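# Constant-signal window: every sample identical, uniform 20 ms spacing.
constant_window <- function(n = 50, ax = 0, ay = 0, az = 0,
                            gx = 0, gy = 0, gz = 0) {
  imu_stream(t_ms = seq(0L, by = 20L, length.out = n),
             ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz)
}

# Linearly separable toy dataset: falls are constant 3 g windows, ADLs
# constant 1 g windows; only svm_mean differs between classes.
toy_dataset <- function(n_per_class = 4) {
  falls <- purrr::map(seq_len(n_per_class),
                      ~ constant_window(ax = 3 + 0.01 * .x))
  adls <- purrr::map(seq_len(n_per_class),
                     ~ constant_window(ax = 1 + 0.01 * .x))
  tibble::tibble(
    activity = rep(c("fall", "adl"), each = n_per_class),
    label = rep(c("FALL", "ADL"), each = n_per_class),
    window = c(falls, adls)
  )
}
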