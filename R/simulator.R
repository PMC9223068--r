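#' Simulator configuration
#'
#' Parameters of the seeded signal generators. The generators emulate the
#' study conditions the detectors were designed for: impact peaks on falls
#' clearly above the 2.5 g trigger, post-impact quiescence longer than the
#' capture-plus-quiescence horizon (1000 + 1500 ms), running peaks spaced
#' closer than that horizon so they cancel each other, and pressure patterns
#' that satisfy their target classification rule with a margin of several
#' noise standard deviations.
#'
#' @param rate_hz IMU and pressure sampling rate (default 50).
#' @param fall_peak_mean,fall_peak_sd Impact-peak magnitude distribution in
#'   g for forward/left/right falls (default 3.2 / 0.4, truncated above
#'   2.6 g so every fall exceeds the 2.5 g trigger).
#' @param backward_peak_mean,backward_peak_sd Softer impact distribution for
#'   backward falls (default 2.8 / 0.2, truncated above 2.55 g); backward
#'   falls end semi-reclined and resemble sitting down, which is the
#'   documented hard case for the classifier.
#' @param quiescence_ms Post-impact still period (default 3000, >= 2600 so
#'   the state machine always completes its quiescence check in-trace).
#' @param adl_peak_interval_ms Spacing of running impacts (default 1500,
#'   < 2500 so successive peaks cancel the pending capture).
#' @param impact_ms Duration of the half-sine impact transient (default 300).
#' @param acc_noise_sd,gyro_noise_sd Additive Gaussian noise on acceleration
#'   (g) and angular velocity (deg/s).
#' @param pressure_levels Named list of `(left, middle, right)` mean counts
#'   per position; defaults satisfy every classification rule with wide
#'   margins.
#' @param pressure_noise_sd Gaussian noise on pressure counts (default 10;
#'   all pattern margins exceed 3 of these).
#' @param pressure_fade_ms Linear cross-fade between pressure holds
#'   (default 400, shorter than the 1 s debounce hold).
#' @param full_scale Pressure ADC full scale (default 1023).
#' @return A `sim_config` list.
#' @export
sim_config <- function(rate_hz = 50,
                       fall_peak_mean = 3.2, fall_peak_sd = 0.4,
                       backward_peak_mean = 2.8, backward_peak_sd = 0.2,
                       quiescence_ms = 3000,
                       adl_peak_interval_ms = 1500,
                       impact_ms = 300,
                       acc_noise_sd = 0.02, gyro_noise_sd = 2,
                       pressure_levels = default_pressure_levels(),
                       pressure_noise_sd = 10,
                       pressure_fade_ms = 400,
                       full_scale = 1023) {
  stopifnot(rate_hz >= 30, fall_peak_mean > 2.5, backward_peak_mean > 2.5,
            quiescence_ms >= 2600, adl_peak_interval_ms < 2500,
            pressure_fade_ms < 1000)
  structure(
    list(rate_hz = rate_hz,
         fall_peak_mean = fall_peak_mean, fall_peak_sd = fall_peak_sd,
         backward_peak_mean = backward_peak_mean,
         backward_peak_sd = backward_peak_sd,
         quiescence_ms = quiescence_ms,
         adl_peak_interval_ms = adl_peak_interval_ms,
         impact_ms = impact_ms,
         acc_noise_sd = acc_noise_sd, gyro_noise_sd = gyro_noise_sd,
         pressure_levels = pressure_levels,
         pressure_noise_sd = pressure_noise_sd,
         pressure_fade_ms = pressure_fade_ms,
         full_scale = full_scale),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @details `default_pressure_levels()` returns the per-position strip means
#'   (counts): middle strip dominant while lying, a single dominant edge
#'   strip while sitting, all near zero when the bed is empty; right-side
#'   positions mirror the left-side ones.
#' @export
default_pressure_levels <- function() {
  list(
    NO_PRESENCE            = c(left = 0,   middle = 0,   right = 0),
    LYING_IN_MIDDLE        = c(left = 300, middle = 700, right = 250),
    LYING_IN_LEFT_EDGE     = c(left = 600, middle = 800, right = 50),
    LYING_IN_RIGHT_EDGE    = c(left = 50,  middle = 800, right = 600),
    SITTING_IN_LEFT_EDGE   = c(left = 900, middle = 300, right = 0),
    SITTING_IN_RIGHT_EDGE  = c(left = 0,   middle = 300, right = 900)
  )
}

# Run expr with a deterministic RNG state, restoring the caller's state.
with_sim_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower | x > upper)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

half_sine <- function(t_ms, start, dur) {
  inside <- t_ms >= start & t_ms <= start + dur
  out <- numeric(length(t_ms))
  out[inside] <- sin(pi * (t_ms[inside] - start) / dur)
  out
}

logistic_ramp <- function(t_ms, center, scale) {
  1 / (1 + exp(-(t_ms - center) / scale))
}

time_grid <- function(duration_ms, rate_hz) {
  step <- round(1000 / rate_hz)
  seq(0L, as.integer(duration_ms), by = as.integer(step))
}

FALL_TYPES <- c("forward", "backward", "left", "right")
ADL_TYPES <- c("hit", "jump", "run_stop", "sit", "pull")

# Resting orientation (unit-ish gravity reading) after each fall type /
# the seated posture; x up, y left, z into the body.
lying_orientation <- function(type) {
  switch(type,
    forward  = c(ax = 0.10, ay = 0.00, az = 0.95),
    backward = c(ax = 0.50, ay = 0.00, az = -0.80),
    left     = c(ax = 0.10, ay = 0.95, az = 0.00),
    right    = c(ax = 0.10, ay = -0.95, az = 0.00),
    sit      = c(ax = 0.60, ay = 0.00, az = -0.75)
  )
}

#' Simulate a fall trace
#'
#' Generates the accelerometer/gyroscope trace of a fall: an upright
#' pre-fall segment, a half-sine impact transient whose dominant lateral
#' axis reflects the fall direction (y for side falls, z for forward and
#' backward ones) and whose peak magnitude always exceeds the 2.5 g trigger,
#' a logistic cross-fade of the gravity reading into the post-fall resting
#' orientation, and a quiescent lying segment long enough for the state
#' machine to complete its check. Deterministic per seed.
#'
#' @param fall_type `"forward"`, `"backward"`, `"left"` or `"right"`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param pre_ms Upright segment duration (default 2000 ms).
#' @return An `imu_stream` tibble; attribute `"truth"` records the type,
#'   impact time and peak.
#' @export
sim_fall_trace <- function(fall_type = FALL_TYPES, config = sim_config(),
                           seed = 1, pre_ms = 2000) {
  fall_type <- match.arg(fall_type, FALL_TYPES)
  with_sim_seed(seed, {
    impact_start <- pre_ms
    dur <- pre_ms + config$impact_ms + config$quiescence_ms
    t <- time_grid(dur, config$rate_hz)
    n <- length(t)

    peak <- if (fall_type == "backward") {
      rtrunc_norm(1, config$backward_peak_mean, config$backward_peak_sd, lower = 2.55)
    } else {
      rtrunc_norm(1, config$fall_peak_mean, config$fall_peak_sd, lower = 2.6)
    }
    rest <- lying_orientation(fall_type) + rnorm(3, 0, 0.05)

    blend <- logistic_ramp(t, impact_start + config$impact_ms / 2, 60)
    ax <- (1 - blend) * 1 + blend * rest["ax"]
    ay <- blend * rest["ay"]
    az <- blend * rest["az"]

    transient <- peak * half_sine(t, impact_start, config$impact_ms)
    axis <- switch(fall_type, forward = "az", backward = "az",
                   left = "ay", right = "ay")
    sgn <- switch(fall_type, forward = 1, backward = -1, left = 1, right = -1)
    if (axis == "ay") ay <- ay + sgn * transient else az <- az + sgn * transient

    gy <- gz <- numeric(n)
    spin <- rtrunc_norm(1, if (fall_type == "backward") 140 else 200, 25, lower = 50)
    rot <- spin * half_sine(t, impact_start, config$impact_ms)
    if (fall_type %in% c("forward", "backward")) gy <- sgn * rot else gz <- sgn * rot

    out <- imu_stream(
      t_ms = t,
      ax = ax + rnorm(n, 0, config$acc_noise_sd),
      ay = ay + rnorm(n, 0, config$acc_noise_sd),
      az = az + rnorm(n, 0, config$acc_noise_sd),
      gx = rnorm(n, 0, config$gyro_noise_sd),
      gy = gy + rnorm(n, 0, config$gyro_noise_sd),
      gz = gz + rnorm(n, 0, config$gyro_noise_sd)
    )
    attr(out, "truth") <- tibble(activity = fall_type, label = "FALL",
                                 impact_t_ms = impact_start, peak_g = peak)
    out
  })
}

#' Simulate an activity-of-daily-living trace
#'
#' The five ADLs of the exercise protocol: `"hit"` (a sharp knock on the
#' sensor while upright), `"jump"` (repeated sub-threshold vertical peaks),
#' `"run_stop"` (supra-threshold vertical impacts spaced closer than the
#' state-machine cancellation horizon, then a stop), `"sit"` (a moderate
#' backward transient settling into a semi-reclined seated posture — the
#' activity that most resembles a backward fall), and `"pull"` (a lateral
#' yank on the sensor). Deterministic per seed.
#'
#' @param adl_type One of `"hit"`, `"jump"`, `"run_stop"`, `"sit"`, `"pull"`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return An `imu_stream` tibble with a `"truth"` attribute.
#' @export
sim_adl_trace <- function(adl_type = ADL_TYPES, config = sim_config(), seed = 1) {
  adl_type <- match.arg(adl_type, ADL_TYPES)
  with_sim_seed(seed, {
    rate <- config$rate_hz
    noise <- function(n, sd) rnorm(n, 0, sd)
    out <- switch(adl_type,
      hit = {
        t <- time_grid(1000 + 60 + config$quiescence_ms, rate)
        a <- rtrunc_norm(1, 3.0, 0.25, lower = 2.6)
        az <- a * half_sine(t, 1000, 60)
        build_imu(t, 1, 0, az, gz = 20 * half_sine(t, 1000, 60), config = config)
      },
      jump = {
        t <- time_grid(5000, rate)
        a <- rtrunc_norm(4, 2.0, 0.15, lower = 1.6, upper = 2.35)
        ax <- rep(1, length(t))
        for (k in seq_len(4)) {
          ax <- ax + (a[k] - 1) * half_sine(t, 600 * k, 200)
        }
        build_imu(t, ax, 0, 0, gy = noise(length(t), 5), config = config)
      },
      run_stop = {
        starts <- 1000 + config$adl_peak_interval_ms * (0:3)
        t <- time_grid(max(starts) + 200 + config$quiescence_ms, rate)
        a <- rtrunc_norm(4, 2.9, 0.15, lower = 2.6)
        ax <- rep(1, length(t))
        for (k in seq_len(4)) {
          ax <- ax + (a[k] - 1) * half_sine(t, starts[k], 200)
        }
        build_imu(t, ax, 0, 0, gy = 30 * half_sine(t, starts[1], 200),
                  config = config)
      },
      sit = {
        pre <- 1500; trans <- 600
        t <- time_grid(pre + trans + config$quiescence_ms, rate)
        rest <- lying_orientation("sit") + rnorm(3, 0, 0.05)
        blend <- logistic_ramp(t, pre + trans / 2, 90)
        a <- rtrunc_norm(1, 2.75, 0.2, lower = 2.55)
        ax <- (1 - blend) * 1 + blend * rest["ax"]
        az <- blend * rest["az"] - a * half_sine(t, pre, trans / 2)
        gy <- -rtrunc_norm(1, 120, 20, lower = 40) * half_sine(t, pre, trans)
        build_imu(t, ax, blend * rest["ay"], az, gy = gy, config = config)
      },
      pull = {
        t <- time_grid(1000 + 120 + config$quiescence_ms, rate)
        a <- rtrunc_norm(1, 2.8, 0.2, lower = 2.6)
        ay <- a * half_sine(t, 1000, 120)
        build_imu(t, 1, ay, 0, gz = 150 * half_sine(t, 1000, 120), config = config)
      }
    )
    attr(out, "truth") <- tibble(activity = adl_type, label = "ADL")
    out
  })
}

build_imu <- function(t, ax, ay, az, gx = 0, gy = 0, gz = 0, config) {
  n <- length(t)
  imu_stream(
    t_ms = t,
    ax = ax + rnorm(n, 0, config$acc_noise_sd),
    ay = ay + rnorm(n, 0, config$acc_noise_sd),
    az = az + rnorm(n, 0, config$acc_noise_sd),
    gx = gx + rnorm(n, 0, config$gyro_noise_sd),
    gy = gy + rnorm(n, 0, config$gyro_noise_sd),
    gz = gz + rnorm(n, 0, config$gyro_noise_sd)
  )
}

#' Simulate a labelled training/testing dataset
#'
#' Generates `n_reps` repetitions of each of the nine protocol activities
#' (five ADLs, four fall types), windows each trace around its strongest
#' peak, and returns a labelled dataset ready for
#' [train_fall_classifier()].
#'
#' @param n_reps Repetitions per activity (default 10).
#' @param config A [sim_config()].
#' @param seed Integer seed; repetition `k` of activity `a` uses a seed
#'   derived deterministically from it.
#' @return A tibble with columns `activity`, `label` and the list-column
#'   `window`.
#' @export
sim_dataset <- function(n_reps = 10, config = sim_config(), seed = 1) {
  acts <- c(ADL_TYPES, FALL_TYPES)
  grid <- tidyr::expand_grid(activity = acts, rep = seq_len(n_reps))
  grid$window <- pmap(list(grid$activity, grid$rep), function(act, k) {
    s <- (seed * 1009L + match(act, acts) * 131L + k) %% .Machine$integer.max
    trace <- if (act %in% FALL_TYPES) {
      sim_fall_trace(act, config, seed = s)
    } else {
      sim_adl_trace(act, config, seed = s)
    }
    trace_window(trace)
  })
  tibble(
    activity = grid$activity,
    label = ifelse(grid$activity %in% FALL_TYPES, "FALL", "ADL"),
    window = grid$window
  )
}

#' Simulate a bed exit (synchronized IMU and pressure streams)
#'
#' Reproduces the canonical bed-exit episode: the wearer lies in the middle
#' of the bed (x near 0, z near 1), rolls to the exit side, sits on the bed
#' edge, stands up (x rising above 0.9 g while z falls inside +/-0.4 g) and
#' walks away. The IMU stream traverses three phases — lying-sitting,
#' sitting-standing, standing-walking — while the synchronized pressure
#' stream steps through LYING_IN_MIDDLE, LYING on the exit side, SITTING on
#' the exit side, and NO_PRESENCE, each held longer than the 1 s debounce.
#'
#' @param side `"left"` or `"right"`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with elements `imu` (an `imu_stream`), `pressure` (a
#'   `pressure_stream`) and `phases` (a tibble of phase names and spans).
#' @examples
#' bx <- sim_bed_exit("left", seed = 7)
#' detect_motion(bx$imu)
#' @export
sim_bed_exit <- function(side = c("left", "right"), config = sim_config(),
                         seed = 1) {
  side <- match.arg(side)
  with_sim_seed(seed, {
    # posture targets: (ax, az) for lying, sitting, standing
    lying <- c(0.05, 0.97); sitting <- c(0.80, 0.50); standing <- c(0.97, 0.05)
    t <- time_grid(8300, config$rate_hz)
    n <- length(t)
    b1 <- logistic_ramp(t, 3500, 120) # lying -> sitting
    b2 <- logistic_ramp(t, 6500, 120) # sitting -> standing
    ax <- lying[1] + (sitting[1] - lying[1]) * b1 + (standing[1] - sitting[1]) * b2
    az <- lying[2] + (sitting[2] - lying[2]) * b1 + (standing[2] - sitting[2]) * b2
    # gentle gait oscillation once walking
    walk <- t >= 7000
    ax[walk] <- ax[walk] + 0.04 * sin(2 * pi * (t[walk] - 7000) / 500)
    sgn <- if (side == "left") 1 else -1
    ay <- sgn * 0.25 * (b1 - b2) # leaning toward the exit side while seated
    imu <- imu_stream(
      t_ms = t,
      ax = ax + rnorm(n, 0, config$acc_noise_sd),
      ay = ay + rnorm(n, 0, config$acc_noise_sd),
      az = az + rnorm(n, 0, config$acc_noise_sd),
      gx = rnorm(n, 0, config$gyro_noise_sd),
      gy = 30 * (half_sine(t, 3200, 600) + half_sine(t, 6200, 600)) +
        rnorm(n, 0, config$gyro_noise_sd),
      gz = rnorm(n, 0, config$gyro_noise_sd)
    )

    side_lab <- toupper(side)
    positions <- c("LYING_IN_MIDDLE",
                   sprintf("LYING_IN_%s_EDGE", side_lab),
                   sprintf("SITTING_IN_%s_EDGE", side_lab),
                   "NO_PRESENCE")
    pressure <- sim_pressure_sequence(
      positions, hold_ms = c(3000, 2000, 2200, 2300),
      config = config, seed = seed + 1L
    )

    phases <- tibble(
      phase = c("lying", "lying-sitting", "sitting", "sitting-standing",
                "standing-walking"),
      start_ms = c(0, 3000, 4000, 6000, 7000),
      end_ms = c(3000, 4000, 6000, 7000, 8300)
    )
    list(imu = imu, pressure = pressure, phases = phases)
  })
}

#' Simulate in-bed rolling (negative control for the movement detector)
#'
#' The wearer rolls from one side to the other repeatedly while staying in
#' bed. Rolling rotates the body about its long (x) axis, so gravity swings
#' between the y and z axes while the x component stays near zero — bounded
#' well below the 0.9 g standing threshold by construction — and the
#' movement detector must stay silent.
#'
#' @param n_rolls Number of side-to-side rolls (default 4).
#' @param roll_period_ms Duration of one roll (default 2000 ms).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return An `imu_stream` tibble.
#' @export
sim_rolling_trace <- function(n_rolls = 4, roll_period_ms = 2000,
                              config = sim_config(), seed = 1) {
  with_sim_seed(seed, {
    t <- time_grid(n_rolls * roll_period_ms, config$rate_hz)
    n <- length(t)
    # roll angle sweeps -60..60 degrees about the long axis
    angle <- (pi / 3) * sin(2 * pi * t / roll_period_ms / 2)
    imu_stream(
      t_ms = t,
      ax = 0.08 + rnorm(n, 0, config$acc_noise_sd),
      ay = sin(angle) + rnorm(n, 0, config$acc_noise_sd),
      az = cos(angle) + rnorm(n, 0, config$acc_noise_sd),
      gx = 60 * cos(2 * pi * t / roll_period_ms / 2) +
        rnorm(n, 0, config$gyro_noise_sd),
      gy = rnorm(n, 0, config$gyro_noise_sd),
      gz = rnorm(n, 0, config$gyro_noise_sd)
    )
  })
}

#' Simulate a pressure-strip sequence for a list of positions
#'
#' Each position is held at its configured per-strip mean levels for its
#' hold time, with Gaussian noise and linear cross-fades between successive
#' holds. Counts are clamped to `[0, full_scale]`. With the default levels
#' and noise, every held pattern satisfies its target classification rule
#' with a margin of several noise standard deviations, so the presence
#' pipeline recovers the requested sequence exactly.
#'
#' @param positions Character vector of positions (no `NOT_RECOGNIZED`).
#' @param hold_ms Hold duration(s) in ms, recycled along `positions`; holds
#'   of 1000 ms or less trigger a warning (the debouncer may never accept
#'   them).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `pressure_stream` tibble; attribute `"truth"` records the
#'   positions and their spans.
#' @export
sim_pressure_sequence <- function(positions, hold_ms = 3000,
                                  config = sim_config(), seed = 1) {
  if (any(!positions %in% names(config$pressure_levels))) {
    abort("unknown position in sequence", class = "bedwatch_validation_error")
  }
  hold_ms <- rep_len(hold_ms, length(positions))
  if (any(hold_ms <= 1000)) {
    warn("holds of 1000 ms or less may never debounce into a stable position")
  }
  with_sim_seed(seed, {
    starts <- cumsum(c(0, head(hold_ms, -1)))
    total <- sum(hold_ms)
    t <- time_grid(total, config$rate_hz)
    n <- length(t)
    lvl <- function(ch) {
      vapply(seq_along(positions), function(k) config$pressure_levels[[positions[k]]][[ch]],
             numeric(1))
    }
    channels <- map(c("left", "middle", "right"), function(ch) {
      v <- lvl(ch)
      base <- v[findInterval(t, starts, rightmost.closed = FALSE)]
      # linear cross-fade at the start of each hold after the first
      for (k in seq_along(positions)[-1]) {
        fade <- t >= starts[k] & t < starts[k] + config$pressure_fade_ms
        frac <- (t[fade] - starts[k]) / config$pressure_fade_ms
        base[fade] <- v[k - 1] + frac * (v[k] - v[k - 1])
      }
      pmin(pmax(base + rnorm(n, 0, config$pressure_noise_sd), 0), config$full_scale)
    })
    out <- pressure_stream(t, channels[[1]], channels[[2]], channels[[3]],
                           full_scale = config$full_scale)
    attr(out, "truth") <- tibble(
      position = positions, start_ms = starts, end_ms = starts + hold_ms
    )
    out
  })
}
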