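# Signal energy/power, SNR, classification metrics, monitoring timelines.

#' Signal energy of the acceleration magnitude over a short window
#'
#' Sums `(ax^2 + ay^2 + az^2)^exponent` over a window starting at `start`
#' (conventionally the moment a force impulse is applied). The literal
#' reporting convention uses `exponent = 2` (the squared magnitude-squared);
#' `exponent = 1` gives the units-consistent energy in g^2 samples.
#'
#' @param seq An [imu_sequence()].
#' @param start Window start in seconds (session time).
#' @param window Window length in seconds (default 0.2).
#' @param exponent 2 (literal, default) or 1.
#' @return Energy value.
#' @export
signal_energy <- function(seq, start = seq$start_time, window = 0.2,
                          exponent = 2) {
  sec <- imu_section(seq, start, window)
  mag2 <- sec$data[, "ax"]^2 + sec$data[, "ay"]^2 + sec$data[, "az"]^2
  sum(mag2^exponent)
}

#' Mean signal power of the acceleration magnitude
#'
#' Default convention is the mean of `ax^2 + ay^2 + az^2` (units g^2, the
#' scale on which the per-class power table is reported); `exponent = 2`
#' gives the literal squared-magnitude-squared mean.
#'
#' @param seq An [imu_sequence()] section.
#' @param exponent 1 (default, g^2) or 2.
#' @return Power value.
#' @export
signal_power <- function(seq, exponent = 1) {
  if (nrow(seq$data) == 0) stop("cannot compute power of an empty section")
  mag2 <- seq$data[, "ax"]^2 + seq$data[, "ay"]^2 + seq$data[, "az"]^2
  mean(mag2^exponent)
}

#' Signal-to-noise ratio from class and noise power
#'
#' @param class_power Mean signal power of an activity class (g^2).
#' @param noise_power Empty-cage noise power (g^2), > 0.
#' @return List with `ratio` and `db` (`10 * log10(ratio)`).
#' @export
snr <- function(class_power, noise_power) {
  if (noise_power <= 0) stop("noise_power must be positive")
  ratio <- class_power / noise_power
  list(ratio = ratio, db = 10 * log10(ratio))
}

#' Per-class power and SNR report
#'
#' @param powers Named numeric vector of per-class mean powers (g^2).
#' @param sds Optional named per-class power standard deviations.
#' @param noise_power Noise floor in g^2.
#' @return `data.frame` of class `power_report`: class, mean power, sd,
#'   SNR ratio and SNR in dB (dB rounded to 2 decimals for reporting).
#' @export
power_report <- function(powers, sds = NULL, noise_power) {
  s <- snr(powers, noise_power)
  df <- data.frame(class = names(powers), power = as.numeric(powers),
                   sd = if (is.null(sds)) NA_real_ else as.numeric(sds),
                   snr_ratio = as.numeric(s$ratio),
                   snr_db = round(as.numeric(s$db), 2))
  attr(df, "noise_power") <- noise_power
  class(df) <- c("power_report", "data.frame")
  df
}

#' Classification metrics: confusion matrix, per-class P/R/F1, averages
#'
#' @param truth,predicted Vectors of equal length with values in `classes`.
#' @param classes Class set and order (default [activity_classes()]).
#' @return List of class `classification_report`: `confusion` (true x
#'   predicted counts), `per_class` (precision, recall, f1, support),
#'   `accuracy`, `macro_f1` (unweighted mean over classes with support),
#'   `weighted_f1` (support-weighted), `n`.
#' @export
classification_metrics <- function(truth, predicted,
                                   classes = activity_classes()) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) {
    stop("label(s) outside the class set: ", paste(bad, collapse = ", "))
  }
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  cm <- table(truth = tf, predicted = pf)
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), NA_real_)
  rec <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec), 0)
  f1[support == 0] <- NA_real_
  per_class <- data.frame(class = classes, precision = as.numeric(prec),
                          recall = as.numeric(rec), f1 = as.numeric(f1),
                          support = as.numeric(support))
  present <- support > 0
  structure(list(
    confusion = cm, per_class = per_class,
    accuracy = sum(tp) / length(truth),
    macro_f1 = mean(f1[present]),
    weighted_f1 = sum(f1[present] * support[present]) / sum(support[present]),
    n = length(truth)), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification report (n =", x$n, ")\n")
  print(x$per_class, row.names = FALSE, digits = 3)
  cat(sprintf("accuracy %.4f | macro F1 %.4f | weighted F1 %.4f\n",
              x$accuracy, x$macro_f1, x$weighted_f1))
  invisible(x)
}

#' F1 score from precision and recall
#' @param precision,recall Values in `[0, 1]`.
#' @return Harmonic mean `2 p r / (p + r)` (0 when both are 0).
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Long-term monitoring timeline
#'
#' Groups labelled sections into consecutive bins (default 3 h) aligned to
#' the session start and reports the relative occurrence of each activity
#' class among the defined (valid, non-Uncertain) sections of each bin.
#'
#' @param sections `data.frame` with `section_start` (or `start`) and
#'   `label` columns, time-ordered.
#' @param bin_hours Bin width in hours (default 3).
#' @param classes Class set (default [activity_classes()]).
#' @return `data.frame` of class `monitoring_timeline`: `bin_start` (s),
#'   `n_defined`, and one fraction column per class (rows with no defined
#'   sections have NA fractions).
#' @export
aggregate_timeline <- function(sections, bin_hours = 3,
                               classes = activity_classes()) {
  start_col <- if ("section_start" %in% names(sections)) "section_start"
    else "start"
  st <- sections[[start_col]]
  lab <- sections$label
  bin_w <- bin_hours * 3600
  bin <- floor(st / bin_w)
  bins <- seq(0, max(bin))
  keep <- lab %in% classes
  out <- data.frame(bin_start = bins * bin_w,
                    n_defined = as.numeric(table(factor(bin[keep],
                                                        levels = bins))))
  for (cl in classes) {
    cnt <- table(factor(bin[keep & lab == cl], levels = bins))
    out[[cl]] <- ifelse(out$n_defined > 0,
                        as.numeric(cnt) / out$n_defined, NA_real_)
  }
  class(out) <- c("monitoring_timeline", "data.frame")
  out
}

#' Dominant period of a timeline fraction series
#'
#' Helper for circadian analysis: returns the period (hours) of the largest
#' non-DC Fourier component of a per-bin fraction series.
#'
#' @param fractions Numeric series (NA bins are mean-imputed).
#' @param bin_hours Bin width in hours.
#' @return Period in hours.
#' @export
dominant_period <- function(fractions, bin_hours = 3) {
  x <- fractions
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  x <- x - mean(x)
  n <- length(x)
  spec <- Mod(stats::fft(x))[2:floor(n / 2 + 1)]
  k <- which.max(spec)
  n * bin_hours / k
}
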