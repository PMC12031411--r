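# build a section of frames with given label mix and velocities
mix_frames <- function(mix, velocity = 0.3, feed = FALSE, n = 270,
                       valid = TRUE) {
  labels <- rep(names(mix), round(unlist(mix) * n))
  labels <- c(labels, rep(names(mix)[1], n - length(labels)))[1:n]
  frame_records((seq_len(n) - 0.5) / 30, rep_len(velocity, n), FALSE,
                rep_len(feed, n), sample(labels), valid = valid)
}

test_that("the decision tree reproduces the documented rule set", {
  th <- reference_thresholds()
  # pure drinking -> Drinking (2/3 majority rule)
  expect_equal(summarize_section(mix_frames(c(Drinking = 1)), th)$label,
               "Drinking")
  # grouped stationary activities reach the majority together
  s <- summarize_section(
    mix_frames(c(Sniffing = 0.3, Grooming = 0.4, Eating = 0.1,
                 Walking = 0.2)), th)
  expect_equal(s$label, "StationaryActivity")
  # resting needs the velocity condition as well
  fast_rest <- mix_frames(c(Resting = 0.85, Sniffing = 0.15),
                          velocity = 0.06)
  expect_equal(summarize_section(fast_rest, th)$label, "Uncertain")
  slow_rest <- mix_frames(c(Resting = 0.85, Sniffing = 0.15),
                          velocity = 0.01)
  expect_equal(summarize_section(slow_rest, th)$label, "Resting")
  # resting inside the feeder is still Resting
  feeder_rest <- mix_frames(c(Resting = 0.9, Sniffing = 0.1),
                            velocity = 0.01, feed = TRUE)
  expect_equal(summarize_section(feeder_rest, th)$label, "Resting")
  # feeder presence above 20% labels active sections ActivityInFeeder
  feeder_act <- mix_frames(c(Eating = 0.6, Grooming = 0.4),
                           velocity = 0.5, feed = TRUE)
  expect_equal(summarize_section(feeder_act, th)$label, "ActivityInFeeder")
  # walking needs the strict 80% majority
  expect_equal(summarize_section(mix_frames(c(Walking = 0.9,
                                              Sniffing = 0.1),
                                            velocity = 3), th)$label,
               "Walking")
  # a 50/50 section satisfies no branch
  expect_equal(summarize_section(mix_frames(c(Walking = 0.5, Resting = 0.5),
                                            velocity = 1), th)$label,
               "Uncertain")
})

test_that("labels depend only on durations, velocity and feeder fraction", {
  fr <- mix_frames(c(Grooming = 0.5, Sniffing = 0.3, Walking = 0.2))
  perm <- fr[sample(nrow(fr)), ]
  perm$timestamp <- fr$timestamp
  perm <- frame_records(perm$timestamp, perm$velocity,
                        perm$around_feed_area_cp, perm$feed_area_cp,
                        perm$label, perm$valid)
  expect_equal(summarize_section(perm)$label, summarize_section(fr)$label)
})

test_that("segmentation yields floor(duration/timeframe) sections", {
  fr <- mix_frames(c(Resting = 1), velocity = 0.01, n = 2700)  # 90 s
  secs <- segment_stream(fr, 9)
  expect_equal(nrow(secs), 10)
  expect_true(all(secs$label == "Resting"))
  # trailing partial window dropped
  fr2 <- mix_frames(c(Resting = 1), velocity = 0.01, n = 2700 + 100)
  expect_equal(nrow(segment_stream(fr2, 9)), 10)
  expect_equal(nrow(segment_stream(fr[0, ], 9)), 0)
})

test_that("all-invalid streams produce only Uncertain sections", {
  fr <- mix_frames(c(Resting = 1), n = 540, valid = FALSE)
  secs <- segment_stream(fr, 9)
  expect_true(all(secs$label == "Uncertain"))
})

test_that("the Uncertain fraction grows with the majority threshold", {
  set.seed(4)
  sched <- default_study_schedule(1, seed = 4)
  sched <- sched[sched$end <= 3600, ]
  cfg <- sim_config(seed = 4)
  fr <- cagevibe:::synth_frames(cfg, sched, 3600)
  fracs <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(m) {
    th <- reference_thresholds(majority = m,
                               strict_majority = max(m, 0.8))
    mean(segment_stream(fr, 9, th)$label == "Uncertain")
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("reference labels recover the generating schedule", {
  sched <- default_study_schedule(1, seed = 5)
  sched <- sched[sched$end <= 3600, ]
  cfg <- sim_config(seed = 5)
  fr <- cagevibe:::synth_frames(cfg, sched, 3600)
  secs <- segment_stream(fr, 9, origin = 0)
  truth <- schedule_sections(sched, 9, total = 3600)
  ok <- truth$label != "Uncertain"
  expect_gte(mean(secs$label[ok] == truth$label[ok]), 0.95)
})
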