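# IMU vibration streams and 30 Hz behaviour-frame exports.
#
# On-disk dialects:
#   * IMU CSV: one comment header line "# sample_rate=<Hz> start_time=<s>
#     units=g,rad/s", then columns ax,ay,az,wx,wy,wz.
#   * frames CSV: header timestamp,velocity,around_feed_area_cp,feed_area_cp,
#     label,valid

#' Construct an IMU sequence
#'
#' An `imu_sequence` is a fixed-rate six-channel vibration record: three
#' accelerometer axes (`ax`, `ay`, `az`, in g) and three gyroscope axes
#' (`wx`, `wy`, `wz`, in rad/s).
#'
#' @param data Numeric matrix (or data frame) with columns `ax, ay, az, wx,
#'   wy, wz`; any column order is accepted and normalised.
#' @param sample_rate Sampling rate in Hz (default 7000).
#' @param start_time Seconds since session start of the first sample.
#' @return An object of class `imu_sequence`: a list with elements `data`
#'   (matrix, canonical column order), `sample_rate` and `start_time`.
#' @export
imu_sequence <- function(data, sample_rate = 7000, start_time = 0) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (is.null(colnames(data))) {
    if (ncol(data) != 6L) stop("unnamed IMU data must have exactly 6 columns")
    colnames(data) <- imu_axes()
  }
  missing <- setdiff(imu_axes(), colnames(data))
  if (length(missing)) {
    stop("IMU data is missing column(s): ", paste(missing, collapse = ", "))
  }
  data <- data[, imu_axes(), drop = FALSE]
  storage.mode(data) <- "double"
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a single positive number")
  }
  if (nrow(data) && any(!is.finite(data))) {
    stop("IMU data contains non-finite samples")
  }
  structure(
    list(data = data, sample_rate = as.numeric(sample_rate),
         start_time = as.numeric(start_time)),
    class = "imu_sequence"
  )
}

#' @export
print.imu_sequence <- function(x, ...) {
  cat(sprintf(
    "<imu_sequence> %d samples x 6 axes @ %g Hz (%.3f s, start %.3f s)\n",
    nrow(x$data), x$sample_rate, nrow(x$data) / x$sample_rate, x$start_time))
  invisible(x)
}

#' Duration of an IMU sequence in seconds
#' @param seq An [imu_sequence()].
#' @return Duration in seconds.
#' @export
imu_duration <- function(seq) nrow(seq$data) / seq$sample_rate

#' Extract a time slice of an IMU sequence
#'
#' @param seq An [imu_sequence()].
#' @param start Start of the slice, seconds since session start.
#' @param duration Length of the slice in seconds.
#' @return An [imu_sequence()] covering `[start, start + duration)`.
#' @export
imu_section <- function(seq, start, duration) {
  i0 <- round((start - seq$start_time) * seq$sample_rate) + 1L
  n <- round(duration * seq$sample_rate)
  if (i0 < 1L || i0 + n - 1L > nrow(seq$data)) {
    stop("requested section [", start, ", ", start + duration,
         ") is outside the sequence")
  }
  imu_sequence(seq$data[i0:(i0 + n - 1L), , drop = FALSE],
               sample_rate = seq$sample_rate, start_time = start)
}

#' Write an IMU sequence to disk
#'
#' @param seq An [imu_sequence()].
#' @param path Output file path.
#' @param format On-disk dialect; `"csv"` is the self-describing comma
#'   dialect with a `# sample_rate=...` header comment.
#' @return `path`, invisibly.
#' @export
write_imu <- function(seq, path, format = c("csv")) {
  format <- match.arg(format)
  stopifnot(inherits(seq, "imu_sequence"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate=%.10g start_time=%.10g units=g,rad/s",
                     seq$sample_rate, seq$start_time), con)
  writeLines(paste(imu_axes(), collapse = ","), con)
  close(con); on.exit(NULL)
  if (nrow(seq$data)) {
    data.table::fwrite(data.table::as.data.table(seq$data), path,
                       append = TRUE, col.names = FALSE)
  }
  invisible(path)
}

#' Read an IMU sequence from disk
#'
#' @param path File written by [write_imu()] (or following its dialect).
#' @param format On-disk dialect (see [write_imu()]).
#' @return An [imu_sequence()]; axis order is normalised to
#'   `ax, ay, az, wx, wy, wz`.
#' @export
read_imu <- function(path, format = c("csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#")) {
    stop("format error: missing '# sample_rate=...' header line in ", path)
  }
  get_field <- function(name, default = NA_real_) {
    m <- regmatches(hdr, regexec(paste0(name, "=([-0-9.eE+]+)"), hdr))[[1]]
    if (length(m) < 2L) default else as.numeric(m[2])
  }
  fs <- get_field("sample_rate")
  if (is.na(fs)) stop("format error: header does not declare sample_rate")
  t0 <- get_field("start_time", 0)
  dt <- data.table::fread(path, skip = 1L, header = TRUE, sep = ",")
  missing <- setdiff(imu_axes(), names(dt))
  if (length(missing)) {
    stop("format error: missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(dt) == 0L) {
    return(imu_sequence(matrix(numeric(0), 0, 6,
                               dimnames = list(NULL, imu_axes())),
                        sample_rate = fs, start_time = t0))
  }
  for (col in imu_axes()) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("parse error: non-numeric value in column '", col, "' at data row ",
           if (is.na(bad)) "?" else bad)
    }
    if (anyNA(v)) {
      stop("parse error: missing value in column '", col, "' at data row ",
           which(is.na(v))[1])
    }
  }
  imu_sequence(as.matrix(dt[, imu_axes(), with = FALSE]),
               sample_rate = fs, start_time = t0)
}

#' Construct a 30 Hz behaviour-frame table
#'
#' One row per video frame of the behaviour-analysis export: timestamp,
#' centre-point velocity (cm/s), feeder-area booleans, raw behaviour label,
#' and a validity flag (FALSE for lost-tracking frames, which downstream
#' steps exclude from all denominators).
#'
#' @param timestamp Seconds since session start, strictly increasing.
#' @param velocity Centre-point velocity in cm/s (`NA` allowed when invalid).
#' @param around_feed_area_cp,feed_area_cp Logical location flags.
#' @param label Raw behaviour label, one of [raw_labels()].
#' @param valid Logical; FALSE marks lost-tracking/invalid frames.
#' @return A `data.frame` of class `frame_records`.
#' @export
frame_records <- function(timestamp, velocity, around_feed_area_cp,
                          feed_area_cp, label, valid = TRUE) {
  label <- as.character(label)
  bad <- setdiff(unique(label), raw_labels())
  if (length(bad)) {
    stop("unknown label(s) ", paste(bad, collapse = ", "),
         "; allowed labels: ", paste(raw_labels(), collapse = ", "))
  }
  df <- data.frame(
    timestamp = as.numeric(timestamp),
    velocity = as.numeric(velocity),
    around_feed_area_cp = as.logical(around_feed_area_cp),
    feed_area_cp = as.logical(feed_area_cp),
    label = label,
    valid = rep_len(as.logical(valid), length(timestamp))
  )
  if (is.unsorted(df$timestamp, strictly = TRUE)) {
    stop("frame timestamps must be strictly increasing")
  }
  df$valid <- df$valid & df$label != "Invalid" &
    !(is.finite(df$velocity) & df$velocity < 0)
  if (any(df$valid & (!is.finite(df$velocity) | df$velocity < 0))) {
    stop("valid frames must have non-negative velocity")
  }
  class(df) <- c("frame_records", "data.frame")
  df
}

#' Write behaviour frames to CSV
#' @param frames A [frame_records()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  data.table::fwrite(as.data.frame(frames), path)
  invisible(path)
}

#' Read behaviour frames from CSV
#'
#' Invalid (lost-tracking) rows are preserved with `valid = FALSE` rather
#' than dropped, so that record counts round-trip.
#'
#' @param path CSV with columns `timestamp, velocity, around_feed_area_cp,
#'   feed_area_cp, label, valid`.
#' @return A [frame_records()] table.
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  dt <- data.table::fread(path, header = TRUE)
  need <- c("timestamp", "velocity", "around_feed_area_cp", "feed_area_cp",
            "label", "valid")
  missing <- setdiff(need, names(dt))
  if (length(missing)) {
    stop("format error: missing column(s): ", paste(missing, collapse = ", "))
  }
  frame_records(dt$timestamp, dt$velocity, dt$around_feed_area_cp,
                dt$feed_area_cp, dt$label, dt$valid)
}

#' Session manifest
#'
#' Bookkeeping record tying one cage's IMU file and frames file together.
#'
#' @param cage_id Cage identifier.
#' @param imu_path,frames_path Paths to the IMU stream and frames CSV.
#' @param duration Session duration in seconds (optional; read from the files
#'   when `NA`).
#' @return A list of class `session_manifest`.
#' @export
session_manifest <- function(cage_id, imu_path, frames_path, duration = NA) {
  for (p in c(imu_path, frames_path)) {
    if (!file.exists(p)) stop("referenced file does not exist: ", p)
  }
  structure(list(cage_id = cage_id, imu_path = imu_path,
                 frames_path = frames_path, duration = duration),
            class = "session_manifest")
}
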