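test_that("zero amplitude yields an all-zero impulse response", {
  r <- impulse_response(beam_model(), 0, 0.1)
  expect_true(all(r == 0))
  expect_error(impulse_response(beam_model(), -1, 0.1), "amplitude")
})

test_that("donor axes are scaled, led copies of the primary axis", {
  # 94 Hz mode: az primary, wx donor at gain 0.039688, quarter-period lead
  beam <- single_mode_beam()
  r <- impulse_response(beam, 1, 0.4)
  s <- floor(7000 / (4 * 94))
  wx_aligned <- phase_shift(r[, "wx"], pi / 2, 94, 7000)
  keep <- (s + 1):nrow(r)
  fit <- stats::lm(wx_aligned[keep] ~ 0 + r[keep, "az"])
  expect_equal(unname(coef(fit)), 0.039688, tolerance = 0.01)
  # normalized cross-correlation after alignment is essentially 1
  expect_gt(cor(wx_aligned[keep], r[keep, "az"]), 0.99)

  # 906 Hz mode: ay primary, wx donor
  beam2 <- single_mode_beam(frequency = 906, gain = 0.027865,
                            primary = "ay", donor = "wx")
  r2 <- impulse_response(beam2, 1, 0.4)
  wx2 <- phase_shift(r2[, "wx"], pi / 2, 906, 7000)
  keep2 <- 3:nrow(r2)
  fit2 <- stats::lm(wx2[keep2] ~ 0 + r2[keep2, "ay"])
  expect_equal(unname(coef(fit2)), 0.027865, tolerance = 0.01)
})

test_that("the response spectrum peaks at the beam mode frequencies", {
  r <- impulse_response(beam_model(), 1, 1)   # 1 s -> 1 Hz bins
  sp_az <- Mod(fft(r[, "az"]))[2:3500]
  expect_equal(which.max(sp_az) + 1 - 1, 94, tolerance = 0.02)
  sp_ay <- Mod(fft(r[, "ay"]))[2:3500]
  expect_equal(which.max(sp_ay) + 1 - 1, 906, tolerance = 0.01)
})

test_that("per-class signal power is calibrated to the study-scale table", {
  targets <- class_power_targets()
  cfg <- sim_config(seed = 42)
  empty <- generate_session(cfg, NULL, duration = 60)
  expect_equal(signal_power(empty$imu), targets[["SensorNoise"]],
               tolerance = 0.25)
  powers <- numeric(0)
  for (cl in activity_classes()) {
    ses <- generate_session(cfg, activity_schedule(cl, 0, 60))
    powers[cl] <- signal_power(ses$imu)
    expect_equal(powers[[cl]], targets[[cl]], tolerance = 0.25,
                 info = cl)
  }
  # monotone ordering Resting < Stationary < Walking < Feeder < Drinking
  expect_true(all(diff(powers) > 0))
})

test_that("identical seeds reproduce sessions bitwise", {
  cfg <- sim_config(seed = 77)
  sched <- activity_schedule(c("Resting", "Drinking"), c(0, 10), c(10, 15))
  s1 <- generate_session(cfg, sched)
  s2 <- generate_session(cfg, sched)
  expect_identical(s1$imu$data, s2$imu$data)
  expect_identical(s1$frames, s2$frames)
})

test_that("overlapping schedules are rejected", {
  expect_error(activity_schedule(c("Resting", "Walking"), c(0, 5), c(10, 15)),
               "overlap")
  expect_error(activity_schedule("Resting", 5, 5), "end > start")
})

test_that("drinking sections carry a ~10 Hz burst train", {
  cfg <- sim_config(seed = 8)
  ses <- generate_session(cfg, activity_schedule("Drinking", 0, 30))
  # burst rate via the envelope of the 94 Hz band detail
  dec <- mldwt_decompose(ses$imu$data[, "az"], sample_rate = 7000)
  env <- abs(dec$details[[6]])                    # ~109 Hz coefficient rate
  env_rate <- 7000 / 2^6
  spec <- Mod(fft(env - mean(env)))
  freqs <- (seq_along(spec) - 1) / length(env) * env_rate
  band <- which(freqs > 5 & freqs < 20)
  peak <- freqs[band[which.max(spec[band])]]
  expect_gt(peak, 8)
  expect_lt(peak, 12)
})

test_that("frame velocities respect the class thresholds", {
  cfg <- sim_config(seed = 12, invalid_rate = 0)
  sched <- activity_schedule(c("Resting", "Walking"), c(0, 30), c(30, 60))
  ses <- generate_session(cfg, sched)
  fr <- ses$frames
  rest <- fr$timestamp < 30
  expect_lt(mean(fr$velocity[rest]), 0.05)
  expect_true(all(fr$velocity[!rest & fr$label == "Walking"] >= 1.5))
  # feeder sections set the feed-area flag
  ses2 <- generate_session(cfg, activity_schedule("ActivityInFeeder", 0, 30))
  expect_gt(mean(ses2$frames$feed_area_cp), 0.2)
})

test_that("multi-day schedules show circadian and acclimatization structure", {
  sched <- default_study_schedule(7, seed = 11)
  expect_s3_class(sched, "activity_schedule")
  expect_equal(max(sched$end), 7 * 86400)
  secs <- schedule_sections(sched, 9)
  tl <- aggregate_timeline(data.frame(section_start = secs$start,
                                      label = secs$label))
  hr <- (tl$bin_start / 3600) %% 24
  light <- hr >= 7 & hr < 19
  # Resting dominates light-phase bins relative to dark-phase bins
  expect_gt(mean(tl$Resting[light], na.rm = TRUE),
            mean(tl$Resting[!light], na.rm = TRUE))
  # elevated activity during the first two days (acclimatization)
  day <- tl$bin_start / 86400
  act <- 1 - tl$Resting
  expect_gt(mean(act[day < 2], na.rm = TRUE),
            mean(act[day >= 2], na.rm = TRUE))
  # Resting is the most frequent class overall
  counts <- table(secs$label[secs$label != "Uncertain"])
  expect_equal(names(which.max(counts)), "Resting")
})

test_that("different seeds give different schedules", {
  expect_false(identical(default_study_schedule(1, seed = 1),
                         default_study_schedule(1, seed = 2)))
})
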