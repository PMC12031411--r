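test_that("signal energy follows the literal summation convention", {
  data <- matrix(0, 7000, 6, dimnames = list(NULL, cagevibe:::imu_axes()))
  data[, "az"] <- 1
  seq <- imu_sequence(data, sample_rate = 7000)
  # 0.2 s at 7 kHz = 1400 samples of (0+0+1)^2
  expect_equal(signal_energy(seq, 0, 0.2), 1400)
  expect_equal(signal_energy(seq, 0, 0.2, exponent = 1), 1400)
  zero <- imu_sequence(matrix(0, 7000, 6))
  expect_equal(signal_energy(zero, 0, 0.2), 0)
  expect_error(signal_energy(seq, 0.95, 0.2), "outside")
})

test_that("energy scales with amplitude^4 (literal) and ^2 (magnitude)", {
  seq <- make_test_imu(n = 7000)
  dbl <- imu_sequence(2 * seq$data, sample_rate = 7000)
  expect_equal(signal_energy(dbl, 0, 0.2) / signal_energy(seq, 0, 0.2), 16,
               tolerance = 1e-9)
  expect_equal(signal_energy(dbl, 0, 0.2, exponent = 1) /
                 signal_energy(seq, 0, 0.2, exponent = 1), 4,
               tolerance = 1e-9)
})

test_that("signal power matches closed forms", {
  g0 <- 0.5
  data <- matrix(0, 1000, 6, dimnames = list(NULL, cagevibe:::imu_axes()))
  data[, "az"] <- g0
  expect_equal(signal_power(imu_sequence(data)), g0^2)
  # white Gaussian axes of sd s give power ~ 3 s^2
  set.seed(2)
  s <- 1e-3
  noise <- matrix(rnorm(6e6, 0, s), 1e6, 6)
  expect_equal(signal_power(imu_sequence(noise)), 3 * s^2,
               tolerance = 0.01)
  expect_error(signal_power(imu_sequence(matrix(numeric(0), 0, 6))),
               "empty")
})

test_that("signal power is quadratic in amplitude", {
  seq <- make_test_imu(n = 5000)
  for (k in c(0.5, 2, 3)) {
    scaled <- imu_sequence(k * seq$data)
    expect_equal(signal_power(scaled) / signal_power(seq), k^2,
                 tolerance = 1e-9)
  }
})

test_that("SNR reproduces the study-scale table rows", {
  r <- snr(8.129e-6, 5.075e-6)
  expect_equal(r$ratio, 1.602, tolerance = 1e-3)
  expect_equal(round(r$db, 2), 2.05)
  d <- snr(213.37e-6, 5.075e-6)
  expect_equal(round(d$db, 2), 16.24)
  same <- snr(3e-6, 3e-6)
  expect_equal(same$ratio, 1)
  expect_equal(same$db, 0)
  expect_error(snr(1, 0), "positive")
})

test_that("dB and ratio stay consistent in power reports", {
  p <- c(Resting = 8.129e-6, Drinking = 213.37e-6)
  rep <- power_report(p, noise_power = 5.075e-6)
  expect_equal(rep$snr_db, round(10 * log10(rep$snr_ratio), 2))
})

test_that("classification metrics satisfy their identities", {
  # harmonic-mean F1 from the study-scale Resting row
  expect_equal(round(f1_score(0.947, 0.863), 3), 0.903)
  set.seed(9)
  classes <- activity_classes()
  truth <- sample(classes, 500, replace = TRUE)
  pred <- truth
  flip <- sample(500, 150)
  pred[flip] <- sample(classes, 150, replace = TRUE)
  rep <- classification_metrics(truth, pred)
  expect_equal(sum(diag(rep$confusion)) / 500, rep$accuracy)
  expect_equal(unname(rowSums(rep$confusion)),
               rep$per_class$support)
  expect_equal(rep$macro_f1, mean(rep$per_class$f1))
  # perfect predictions
  perf <- classification_metrics(truth, truth)
  expect_equal(perf$accuracy, 1)
  expect_true(all(perf$per_class$f1 == 1))
  expect_true(all(perf$confusion[row(perf$confusion) !=
                                   col(perf$confusion)] == 0))
  expect_error(classification_metrics(truth, rep("Flying", 500)), "class set")
})

test_that("degenerate one-class predictions give the closed-form macro F1", {
  classes <- activity_classes()
  truth <- rep(classes, each = 20)
  pred <- rep("Resting", 100)
  rep_ <- classification_metrics(truth, pred)
  expect_equal(rep_$accuracy, 0.2)
  expect_equal(rep_$macro_f1, (2 * 0.2 / 1.2) / 5, tolerance = 1e-9)
})

test_that("metrics agree with an independent implementation", {
  skip_if_not_installed("caret")
  set.seed(10)
  classes <- activity_classes()
  truth <- factor(sample(classes, 300, replace = TRUE), levels = classes)
  pred <- factor(sample(classes, 300, replace = TRUE), levels = classes)
  mine <- classification_metrics(as.character(truth), as.character(pred))
  ref <- caret::confusionMatrix(pred, truth, mode = "prec_recall")
  expect_equal(mine$accuracy, unname(ref$overall["Accuracy"]))
  expect_equal(mine$per_class$precision,
               unname(ref$byClass[, "Precision"]), tolerance = 1e-12)
  expect_equal(mine$per_class$recall,
               unname(ref$byClass[, "Recall"]), tolerance = 1e-12)
})

test_that("weighted F1 equals macro F1 at equal support", {
  classes <- activity_classes()
  set.seed(12)
  truth <- rep(classes, each = 30)
  pred <- truth
  pred[sample(150, 40)] <- sample(classes, 40, replace = TRUE)
  rep_ <- classification_metrics(truth, pred)
  expect_equal(rep_$macro_f1, rep_$weighted_f1, tolerance = 1e-12)
})

test_that("timelines report per-bin relative occurrence", {
  secs <- data.frame(
    section_start = seq(0, 86400 - 9, by = 9),
    label = "Resting")
  tl <- aggregate_timeline(secs)
  expect_equal(nrow(tl), 8)               # 24 h / 3 h
  expect_true(all(tl$Resting == 1))
  expect_true(all(abs(rowSums(tl[, activity_classes()]) - 1) < 1e-12))
  # uncertain-only bins stay empty
  secs$label[secs$section_start < 10800] <- "Uncertain"
  tl2 <- aggregate_timeline(secs)
  expect_equal(tl2$n_defined[1], 0)
  expect_true(is.na(tl2$Resting[1]))
})

test_that("dominant_period finds a planted 24 h cycle", {
  bins <- 0:55
  frac <- 0.6 + 0.3 * cos(2 * pi * bins * 3 / 24)
  expect_equal(dominant_period(frac, 3), 24)
})
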