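# Reference labelling: collapse 30 Hz behaviour frames into one activity
# label per analysis time frame with a threshold decision tree.

#' Decision-tree thresholds
#'
#' @param majority Relative-duration majority required for Drinking and for
#'   the grouped Stationary Activity classes (default 0.67, a 2/3 majority).
#' @param strict_majority Stricter majority for Resting and Walking
#'   (default 0.80).
#' @param resting_velocity Mean-velocity ceiling for Resting in cm/s
#'   (default 0.05); separates true rest from very low-intensity activity.
#' @param feeder_presence Fraction of frames with the centre point inside
#'   the feed rack required for Activity in Feeder (default 0.20).
#' @param min_valid Minimum fraction of valid (tracked) frames for a
#'   section to be labelled at all (default 0.5).
#' @return A list of class `reference_thresholds`.
#' @export
reference_thresholds <- function(majority = 0.67, strict_majority = 0.80,
                                 resting_velocity = 0.05,
                                 feeder_presence = 0.20, min_valid = 0.5) {
  stopifnot(majority > 0, majority <= 1, strict_majority > 0,
            strict_majority <= 1, resting_velocity > 0,
            feeder_presence > 0, feeder_presence <= 1)
  structure(list(majority = majority, strict_majority = strict_majority,
                 resting_velocity = resting_velocity,
                 feeder_presence = feeder_presence, min_valid = min_valid),
            class = "reference_thresholds")
}

# raw labels feeding the grouped Stationary Activity class
stationary_group <- function() c("Grooming", "Sniffing", "Eating")

#' Summarize one section of behaviour frames into a single activity label
#'
#' Computes the relative duration of each raw activity over the valid
#' frames of the section, then walks an ordered rule list: (1) Drinking if
#' its share reaches the 2/3 majority; (2) Resting if its share reaches the
#' strict majority and the mean velocity stays below the resting ceiling
#' (resting inside the feeder is still Resting); (3) Activity in Feeder if
#' the feed-rack presence reaches its threshold; (4) Walking at the strict
#' majority; (5) Stationary Activity if grooming + sniffing + eating
#' together reach the 2/3 majority; otherwise (6) Uncertain. Sections with
#' too few valid frames are Uncertain.
#'
#' @param frames [frame_records()] rows spanning one section.
#' @param thresholds A [reference_thresholds()].
#' @return A list of class `section_summary`: `label`,
#'   `relative_durations` (named, over valid frames), `mean_velocity`,
#'   `feed_area_fraction`, `valid_fraction`, `n_frames`.
#' @export
summarize_section <- function(frames, thresholds = reference_thresholds()) {
  n <- nrow(frames)
  v <- frames$valid
  nv <- sum(v)
  rel <- stats::setNames(numeric(length(raw_labels())), raw_labels())
  if (nv > 0) {
    tab <- table(factor(frames$label[v], levels = raw_labels()))
    rel[] <- as.numeric(tab) / nv
  }
  mean_vel <- if (nv > 0) mean(frames$velocity[v], na.rm = TRUE) else NA_real_
  feed_frac <- if (nv > 0) mean(frames$feed_area_cp[v]) else NA_real_
  label <- "Uncertain"
  if (n > 0 && nv > 0 && nv / n >= thresholds$min_valid) {
    stat_frac <- sum(rel[stationary_group()])
    if (rel[["Drinking"]] >= thresholds$majority) {
      label <- "Drinking"
    } else if (rel[["Resting"]] >= thresholds$strict_majority &&
               mean_vel < thresholds$resting_velocity) {
      label <- "Resting"
    } else if (feed_frac >= thresholds$feeder_presence) {
      label <- "ActivityInFeeder"
    } else if (rel[["Walking"]] >= thresholds$strict_majority) {
      label <- "Walking"
    } else if (stat_frac >= thresholds$majority) {
      label <- "StationaryActivity"
    }
  }
  structure(list(label = label, relative_durations = rel,
                 mean_velocity = mean_vel, feed_area_fraction = feed_frac,
                 valid_fraction = if (n > 0) nv / n else 0, n_frames = n),
            class = "section_summary")
}

#' Segment a frame stream into labelled sections
#'
#' Splits the stream into consecutive non-overlapping `timeframe`-second
#' windows starting at the first frame's window origin, labels each with
#' [summarize_section()], and drops the trailing partial window. Uncertain
#' sections are kept in the output (flagged by their label) so callers can
#' exclude them from training and evaluation.
#'
#' @param frames A [frame_records()] stream.
#' @param timeframe Section length in seconds.
#' @param thresholds A [reference_thresholds()].
#' @param origin Session start time; defaults to the first frame's
#'   timestamp floored to the frame period.
#' @return `data.frame` with `section_start`, `section_end`, `label`,
#'   `mean_velocity`, `valid_fraction`.
#' @export
segment_stream <- function(frames, timeframe,
                           thresholds = reference_thresholds(),
                           origin = NULL) {
  stopifnot(timeframe > 0)
  if (nrow(frames) == 0) {
    return(data.frame(section_start = numeric(0), section_end = numeric(0),
                      label = character(0), mean_velocity = numeric(0),
                      valid_fraction = numeric(0)))
  }
  period <- if (nrow(frames) > 1) stats::median(diff(frames$timestamp)) else
    1 / 30
  if (is.null(origin)) {
    origin <- frames$timestamp[1] - frames$timestamp[1] %% period
  }
  span <- max(frames$timestamp) + period - origin
  n_sec <- floor(span / timeframe + 1e-9)
  sec <- findInterval(frames$timestamp, origin + (0:n_sec) * timeframe)
  groups <- split(seq_len(nrow(frames)), factor(sec, levels = seq_len(n_sec)))
  label <- character(n_sec)
  mean_velocity <- valid_fraction <- numeric(n_sec)
  for (i in seq_len(n_sec)) {
    s <- summarize_section(frames[groups[[i]], , drop = FALSE], thresholds)
    label[i] <- s$label
    mean_velocity[i] <- s$mean_velocity
    valid_fraction[i] <- s$valid_fraction
  }
  data.frame(section_start = origin + (seq_len(n_sec) - 1) * timeframe,
             section_end = origin + seq_len(n_sec) * timeframe,
             label = label, mean_velocity = mean_velocity,
             valid_fraction = valid_fraction)
}
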