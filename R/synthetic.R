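# Synthetic tuned-beam IMU sessions with a paired 30 Hz behaviour stream.
#
# The simulator emulates the signal structure a resonant-beam IMU mount
# produces in a mouse home cage: every force impulse the animal applies
# rings the beam's oscillation modes (94 Hz vertical bending, 906 Hz), each
# mode couples a fixed pair of sensor axes with a fixed relative amplitude
# and a quarter-period phase offset, and uncorrelated Gaussian sensor noise
# overlays everything. Activities differ in their impulse timing (regular
# ~10 Hz trains while drinking, sparse intermittent steps while walking,
# irregular strokes during stationary activity, high-rate rattling in the
# metal feeder) and in their mean signal power, which is calibrated
# per class to the study-scale power table in `class_power_targets()`.

#' Beam oscillation-mode model
#'
#' @param modes List of modes; each a list with `frequency` (Hz),
#'   `damping_ratio` (fraction of critical, in (0,1)), `gains` (length-6
#'   per-axis amplitude gains, order `ax, ay, az, wx, wy, wz`) and `phases`
#'   (length-6 radians). Donor axes lead the unit-gain axis by
#'   `floor(phase * FS / (2 pi f))` samples, matching the alignment rule the
#'   fusion stage undoes.
#' @param noise_sd Length-6 per-axis noise standard deviations (g for
#'   accelerometers, rad/s for gyroscopes).
#' @param sample_rate Sampling rate the model will be rendered at (Hz).
#' @return A list of class `beam_model`.
#' @export
beam_model <- function(modes = default_beam_modes(),
                       noise_sd = default_noise_sd(),
                       sample_rate = 7000) {
  for (m in modes) {
    stopifnot(m$frequency > 0, m$frequency < sample_rate / 2,
              m$damping_ratio > 0, m$damping_ratio < 1,
              length(m$gains) == 6L, length(m$phases) == 6L)
  }
  stopifnot(length(noise_sd) == 6L, all(noise_sd >= 0))
  names(noise_sd) <- imu_axes()
  modes <- lapply(modes, function(m) {
    names(m$gains) <- names(m$phases) <- imu_axes()
    m
  })
  structure(list(modes = modes, noise_sd = noise_sd,
                 sample_rate = sample_rate),
            class = "beam_model")
}

#' @rdname beam_model
#' @export
default_beam_modes <- function() {
  list(
    # vertical bending: az primary, wx coupled at quarter-period lead;
    # a small wy leakage gives the fourth classification axis signal
    list(frequency = 94, damping_ratio = 0.02,
         gains = c(0.15, 0, 1, 0.039688, 0.02, 0),
         phases = c(0, 0, 0, pi / 2, 0, 0)),
    # lateral mode: ay primary, wx coupled
    list(frequency = 906, damping_ratio = 0.02,
         gains = c(0.1, 1, 0, 0.027865, 0.015, 0),
         phases = c(0, 0, 0, pi / 2, 0, 0))
  )
}

#' @rdname beam_model
#' @export
default_noise_sd <- function() {
  # accelerometer sd calibrated so empty-cage power E[ax^2+ay^2+az^2]
  # matches the 5.075e-6 g^2 noise floor; gyro sd scaled with the modal
  # coupling gains so donor channels have a comparable SNR
  acc <- sqrt(5.075e-6 / 3)
  c(acc, acc, acc, 0.039688 * acc, 0.03 * acc, 0.03 * acc)
}

#' Per-class mean signal power targets
#'
#' Mean power of the acceleration magnitude (g^2) for each activity class
#' plus the empty-cage noise floor, at study scale. The ordering is strictly
#' increasing from Resting to Drinking.
#'
#' @return Named numeric vector in g^2.
#' @export
class_power_targets <- function() {
  c(SensorNoise = 5.075e-6, Resting = 8.129e-6,
    StationaryActivity = 21.858e-6, Walking = 66.577e-6,
    ActivityInFeeder = 91.967e-6, Drinking = 213.37e-6)
}

#' Simulation configuration
#'
#' @param sample_rate IMU sampling rate in Hz (default 7000).
#' @param frame_rate Behaviour frame rate in Hz (default 30).
#' @param seed Integer seed making the whole session reproducible.
#' @param beam A [beam_model()].
#' @param power_targets Named per-class mean-power targets in g^2; must be
#'   increasing Resting < StationaryActivity < Walking < ActivityInFeeder <
#'   Drinking.
#' @param amp_jitter_sdlog Log-sd of the per-burst log-normal amplitude
#'   jitter reproducing the large within-class power spread.
#' @param invalid_rate Fraction of behaviour frames marked invalid
#'   (lost tracking).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sample_rate = 7000, frame_rate = 30, seed = 1,
                       beam = beam_model(sample_rate = sample_rate),
                       power_targets = class_power_targets(),
                       amp_jitter_sdlog = 0.5, invalid_rate = 0.005) {
  cls <- activity_classes()
  p <- power_targets[cls]
  if (any(is.na(p)) || any(diff(p) <= 0)) {
    stop("power_targets must be increasing over ",
         paste(cls, collapse = " < "))
  }
  structure(list(sample_rate = sample_rate, frame_rate = frame_rate,
                 seed = as.integer(seed), beam = beam,
                 power_targets = power_targets,
                 amp_jitter_sdlog = amp_jitter_sdlog,
                 invalid_rate = invalid_rate),
            class = "sim_config")
}

#' Activity schedule
#'
#' @param label Activity class per entry (no `"Uncertain"`).
#' @param start,end Entry bounds in seconds; entries must not overlap.
#' @param intensity Relative amplitude scale (default 1).
#' @param location One of `"floor"`, `"feeder"`, `"water"`.
#' @return A `data.frame` of class `activity_schedule`, sorted by start.
#' @export
activity_schedule <- function(label, start, end, intensity = 1,
                              location = NULL) {
  bad <- setdiff(unique(label), activity_classes())
  if (length(bad)) stop("invalid schedule label(s): ", paste(bad, collapse = ", "))
  if (is.null(location)) {
    location <- c(Resting = "floor", StationaryActivity = "floor",
                  Walking = "floor", ActivityInFeeder = "feeder",
                  Drinking = "water")[label]
  }
  df <- data.frame(label = as.character(label), start = as.numeric(start),
                   end = as.numeric(end),
                   intensity = rep_len(intensity, length(label)),
                   location = as.character(location))
  if (any(df$end <= df$start)) stop("schedule entries must have end > start")
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)] - 1e-9)) {
    stop("schedule entries overlap")
  }
  rownames(df) <- NULL
  class(df) <- c("activity_schedule", "data.frame")
  df
}

#' Impulse response of the beam model
#'
#' The response of every axis to one unit force impulse: each mode
#' contributes an exponentially decaying sinusoid; a donor axis's trace is
#' the unit-gain axis's trace scaled by the coupling gain and led by the
#' mode's phase offset (in whole samples).
#'
#' @param beam A [beam_model()].
#' @param amplitude Positive amplitude scale in g.
#' @param t Response duration in seconds.
#' @param mode_weights Optional per-mode excitation weights (activities
#'   excite the modes differently; rattling in the metal feeder drives the
#'   high-frequency mode much harder than floor contact does).
#' @return Numeric matrix (samples x 6 axes).
#' @export
impulse_response <- function(beam, amplitude, t,
                             mode_weights = rep(1, length(beam$modes))) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  stopifnot(t > 0)
  fs <- beam$sample_rate
  n <- max(1L, round(t * fs))
  out <- matrix(0, n, 6L, dimnames = list(NULL, imu_axes()))
  if (amplitude == 0) return(out)
  tt <- (seq_len(n) - 1L) / fs
  for (j in seq_along(beam$modes)) {
    m <- beam$modes[[j]]
    if (mode_weights[j] == 0) next
    lam <- 2 * pi * m$frequency * m$damping_ratio
    lead <- floor(m$phases * fs / (2 * pi * m$frequency))
    # base waveform, long enough to cover the largest lead
    ext <- max(lead) + n
    w <- exp(-lam * (seq_len(ext) - 1L) / fs) *
      sin(2 * pi * m$frequency * (seq_len(ext) - 1L) / fs)
    for (ax in which(m$gains != 0)) {
      out[, ax] <- out[, ax] +
        amplitude * mode_weights[j] * m$gains[ax] * w[seq_len(n) + lead[ax]]
    }
  }
  out
}

# per-class burst-process parameters: event timing model and mode mix
class_burst_profile <- function(label) {
  switch(label,
    Resting = list(kind = "poisson", rate = 0.5, mode_weights = c(1, 0.2)),
    StationaryActivity = list(kind = "poisson", rate = 3,
                              mode_weights = c(1, 0.3)),
    Walking = list(kind = "bouts", step_rate = 5, bout_mean = 1,
                   gap_mean = 1.2, mode_weights = c(1, 0.2)),
    ActivityInFeeder = list(kind = "poisson", rate = 6,
                            mode_weights = c(0.35, 1)),
    Drinking = list(kind = "train", rate_range = c(9, 11), jitter = 0.004,
                    mode_weights = c(1, 0.15)),
    stop("no burst profile for label ", label)
  )
}

# event times (s, relative to segment start) for one schedule entry
draw_burst_times <- function(profile, duration) {
  if (profile$kind == "poisson") {
    n_exp <- profile$rate * duration
    gaps <- rexp(ceiling(n_exp + 4 * sqrt(n_exp) + 10), rate = profile$rate)
    tt <- cumsum(gaps)
    tt[tt < duration]
  } else if (profile$kind == "train") {
    rate <- runif(1, profile$rate_range[1], profile$rate_range[2])
    tt <- seq(runif(1, 0, 1 / rate), duration, by = 1 / rate)
    tt + rnorm(length(tt), 0, profile$jitter)
  } else {  # bouts of stepping separated by pauses
    tt <- numeric(0)
    t0 <- runif(1, 0, profile$gap_mean)
    while (t0 < duration) {
      bout <- rexp(1, 1 / profile$bout_mean)
      steps <- seq(0, bout, by = 1 / profile$step_rate)
      tt <- c(tt, t0 + steps)
      t0 <- t0 + bout + rexp(1, 1 / profile$gap_mean)
    }
    tt[tt >= 0 & tt < duration]
  }
}

# raw-label mix emitted by the behaviour tracker during each activity
class_frame_profile <- function(label) {
  switch(label,
    Resting = list(labels = c(Resting = 0.96, Sniffing = 0.04),
                   vel = c(0, 0.04), feed = 0, around = 0),
    StationaryActivity = list(
      labels = c(Grooming = 0.45, Sniffing = 0.35, Eating = 0.18,
                 Movement = 0.02),
      vel = c(0.05, 1.0), feed = 0, around = 0.05),
    Walking = list(labels = c(Walking = 0.88, Sniffing = 0.06,
                              Movement = 0.06),
                   vel = c(2, 10), feed = 0, around = 0.1),
    ActivityInFeeder = list(
      labels = c(Eating = 0.5, Grooming = 0.2, Movement = 0.15,
                 Sniffing = 0.15),
      vel = c(0.1, 2), feed = 0.8, around = 0.95),
    Drinking = list(labels = c(Drinking = 0.92, Sniffing = 0.08),
                    vel = c(0, 0.5), feed = 0, around = 0),
    stop("no frame profile for label ", label)
  )
}

#' Generate a synthetic session: IMU stream plus behaviour frames
#'
#' Renders per-axis Gaussian sensor noise for the whole session, then adds
#' the burst processes of each schedule entry, with per-entry amplitudes
#' calibrated so the mean acceleration-magnitude power of the entry matches
#' its class power target. A paired 30 Hz frame stream encodes matching raw
#' labels, centre-point velocities and feeder-area flags.
#'
#' @param config A [sim_config()].
#' @param schedule An [activity_schedule()]; an empty schedule (zero rows)
#'   yields an empty-cage (noise-only) recording.
#' @param duration Session length in seconds; defaults to the schedule end.
#' @return List with elements `imu` ([imu_sequence()]), `frames`
#'   ([frame_records()]) and `schedule`.
#' @export
generate_session <- function(config, schedule = NULL, duration = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(schedule) || nrow(schedule) == 0) {
    schedule <- activity_schedule(character(0), numeric(0), numeric(0))
  } else if (!inherits(schedule, "activity_schedule")) {
    schedule <- activity_schedule(schedule$label, schedule$start,
                                  schedule$end,
                                  intensity = schedule$intensity %||% 1,
                                  location = schedule$location %||% NULL)
  }
  if (is.null(duration)) {
    duration <- if (nrow(schedule)) max(schedule$end) else
      stop("duration is required for an empty schedule")
  }
  if (nrow(schedule) && max(schedule$end) > duration + 1e-9) {
    stop("schedule extends past the session duration")
  }
  set.seed(config$seed)
  fs <- config$sample_rate
  n <- round(duration * fs)
  noise_power <- sum(config$beam$noise_sd[1:3]^2)
  data <- matrix(0, n, 6L, dimnames = list(NULL, imu_axes()))
  for (i in 1:6) data[, i] <- rnorm(n, 0, config$beam$noise_sd[i])

  resp_dur <- 0.45   # s; decayed to ~e^-5 for the default 94 Hz damping
  for (e in seq_len(nrow(schedule))) {
    lab <- schedule$label[e]
    t0 <- schedule$start[e]
    dur <- schedule$end[e] - t0
    prof <- class_burst_profile(lab)
    tt <- draw_burst_times(prof, dur)
    tt <- tt[tt >= 0 & tt < dur - 2 / fs]
    if (!length(tt)) next
    amp <- rlnorm(length(tt), meanlog = -config$amp_jitter_sdlog^2,
                  sdlog = config$amp_jitter_sdlog)
    block <- matrix(0, round(dur * fs), 6L)
    # unit-amplitude response template, shared by all events of the entry
    tmpl <- impulse_response(config$beam, 1, resp_dur,
                             mode_weights = prof$mode_weights)
    for (b in seq_along(tt)) {
      i0 <- round(tt[b] * fs) + 1L
      len <- min(nrow(tmpl), nrow(block) - i0 + 1L)
      ii <- i0:(i0 + len - 1L)
      block[ii, ] <- block[ii, ] + amp[b] * tmpl[seq_len(len), ]
    }
    # calibrate the burst power (acceleration magnitude) to the class target
    p_target <- config$power_targets[[lab]] - noise_power
    p_burst <- mean(block[, 1]^2 + block[, 2]^2 + block[, 3]^2)
    if (p_burst > 0 && p_target > 0) {
      block <- block * sqrt(p_target / p_burst) * schedule$intensity[e]
    }
    i0 <- round(t0 * fs) + 1L
    ii <- i0:min(i0 + nrow(block) - 1L, n)
    data[ii, ] <- data[ii, ] + block[seq_along(ii), ]
  }

  imu <- imu_sequence(data, sample_rate = fs, start_time = 0)
  frames <- synth_frames(config, schedule, duration)
  list(imu = imu, frames = frames, schedule = schedule)
}

# paired 30 Hz behaviour-frame stream for a schedule
synth_frames <- function(config, schedule, duration) {
  fr <- config$frame_rate
  ts <- seq(0, duration - 1 / fr, by = 1 / fr) + 1 / (2 * fr)
  nf <- length(ts)
  lab <- rep("Resting", nf)
  vel <- runif(nf, 0, 0.03)
  feed <- around <- rep(FALSE, nf)
  if (nrow(schedule)) {
    ent <- findInterval(ts, schedule$start)
    inside <- ent >= 1 & ts < schedule$end[pmax(ent, 1)]
    for (e in unique(ent[inside])) {
      sel <- which(ent == e & inside)
      prof <- class_frame_profile(schedule$label[e])
      lab[sel] <- sample(names(prof$labels), length(sel), replace = TRUE,
                         prob = prof$labels)
      vel[sel] <- runif(length(sel), prof$vel[1], prof$vel[2])
      feed[sel] <- runif(length(sel)) < prof$feed
      around[sel] <- runif(length(sel)) < prof$around
    }
  }
  invalid <- runif(nf) < config$invalid_rate
  lab[invalid] <- "Invalid"
  vel[invalid] <- NA_real_
  frame_records(ts, vel, around, feed, lab, valid = !invalid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a multi-day study schedule with circadian structure
#'
#' Draws a sequence of non-overlapping activity bouts whose class mix
#' follows a 24 h light/dark cycle (12 h light phase starting at 07:00,
#' higher activity in the dark phase) plus an elevated-activity
#' acclimatization phase over the first two days, after which activity
#' settles. Resting bouts are long and dominate the light phase; Walking
#' bouts are short and rare, matching the study-scale class frequencies.
#'
#' @param days Number of days (>= 1).
#' @param seed Integer seed.
#' @return An [activity_schedule()] spanning `days * 86400` seconds.
#' @export
default_study_schedule <- function(days, seed = 1) {
  stopifnot(days >= 1)
  set.seed(seed)
  total <- days * 86400
  # time share of each class by phase (light / dark)
  share_light <- c(Resting = 0.85, StationaryActivity = 0.09,
                   Walking = 0.02, ActivityInFeeder = 0.025,
                   Drinking = 0.015)
  share_dark <- c(Resting = 0.35, StationaryActivity = 0.38,
                  Walking = 0.12, ActivityInFeeder = 0.10,
                  Drinking = 0.05)
  dur_mean <- c(Resting = 240, StationaryActivity = 35, Walking = 6,
                ActivityInFeeder = 25, Drinking = 8)
  labels <- character(0); starts <- ends <- numeric(0)
  t0 <- 0
  while (t0 < total) {
    hour <- (t0 / 3600) %% 24
    light <- hour >= 7 & hour < 19
    share <- if (light) share_light else share_dark
    # acclimatization: extra non-Resting activity decaying over ~2 days
    boost <- 1 + 1.5 * exp(-(t0 / 3600) / 36)
    w <- share
    w[-1] <- w[-1] * boost
    w <- w / sum(w)
    # convert time shares to bout-count weights
    w_bout <- w / dur_mean[names(w)]
    lab <- sample(names(w), 1, prob = w_bout / sum(w_bout))
    dur <- rexp(1, 1 / dur_mean[[lab]]) + 2
    dur <- min(dur, total - t0)
    labels <- c(labels, lab); starts <- c(starts, t0); ends <- c(ends, t0 + dur)
    t0 <- t0 + dur
  }
  activity_schedule(labels, starts, ends)
}

#' Section labels implied by a schedule
#'
#' Splits `[0, max(end))` into consecutive `timeframe`-second sections and
#' labels each with the schedule entry that covers it entirely; sections
#' spanning an entry boundary get `"Uncertain"`. This is the generator-side
#' ground truth that reference labels and classifier output are scored
#' against.
#'
#' @param schedule An [activity_schedule()].
#' @param timeframe Section length in seconds.
#' @param total Session span in seconds (default: the schedule end).
#' @return `data.frame` with `start`, `end`, `label`.
#' @export
schedule_sections <- function(schedule, timeframe, total = max(schedule$end)) {
  n <- floor(total / timeframe)
  start <- (seq_len(n) - 1) * timeframe
  end <- start + timeframe
  i1 <- findInterval(start + 1e-9, schedule$start)
  i2 <- findInterval(end - 1e-9, schedule$start)
  lab <- rep("Uncertain", n)
  same <- i1 == i2 & i1 >= 1
  covered <- same & end - 1e-9 <= schedule$end[pmax(i1, 1)]
  lab[covered] <- schedule$label[i1[covered]]
  data.frame(start = start, end = end, label = lab)
}
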