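# Feature extraction: MLDWT details -> max-pool resampling to a common 200 Hz
# grid -> per-row normalization -> classifier input matrix.

#' Resample a detail component to a fixed length by pooling or repetition
#'
#' Detail components of different decomposition levels have different
#' lengths; resampling them all to `M = 200 Hz * timeframe` samples lets them
#' be stacked into one matrix. For `M < N`, element `m` pools the block
#' `floor((m-1)N/M)+1 .. floor(mN/M)` of the input; for `M >= N`, each input
#' value is repeated across its block.
#'
#' @param x Numeric coefficient vector of length `N >= 1`.
#' @param M Target length.
#' @param pool Pooling rule for the downsampling case: `"absmax"` (default)
#'   keeps the signed value of largest magnitude in each block, preserving
#'   burst amplitude of zero-mean coefficients; `"max"` is the plain maximum.
#' @return Numeric vector of length `M`.
#' @export
resample_detail <- function(x, M, pool = c("absmax", "max")) {
  pool <- match.arg(pool)
  N <- length(x)
  if (N < 1L) stop("empty input: need at least one coefficient")
  stopifnot(M >= 1)
  M <- as.integer(M)
  N_ <- as.numeric(N)   # exact integer division on doubles, no int overflow
  if (M >= N) {
    # block repetition: output m takes x[ceiling(m * N / M)]
    return(x[(seq_len(M) * N_ + M - 1) %/% M])
  }
  lo <- ((seq_len(M) - 1) * N_) %/% M + 1
  hi <- (seq_len(M) * N_) %/% M
  width <- max(hi - lo) + 1L
  # uniform index matrix; short blocks repeat their last element, which
  # changes neither max nor absmax
  idx <- outer(seq_len(width) - 1L, as.integer(lo), `+`)
  idx <- pmin(idx, rep(as.integer(hi), each = width))
  A <- x[idx]
  dim(A) <- c(width, M)
  if (pool == "max") {
    do.call(pmax, lapply(seq_len(width), function(i) A[i, ]))
  } else {
    j <- max.col(t(abs(A)), ties.method = "first")
    A[cbind(j, seq_len(M))]
  }
}

#' Build the classifier feature matrix for one analysis section
#'
#' Decomposes the selected sensor axes with [mldwt_decompose()], optionally
#' replaces resonance-coupled detail rows with their fused versions
#' ([apply_fusion()]), resamples every detail component to `rate *
#' timeframe` samples with [resample_detail()], and normalizes each row.
#' Rows are ordered axis-major: all levels (finest first) of the first axis,
#' then the second axis, and so on — with the default four axes and 10
#' levels, a 40-row matrix.
#'
#' @param seq An [imu_sequence()] section whose duration equals `timeframe`.
#' @param axes Sensor axes used for classification (default
#'   `c("ax", "ay", "az", "wy")`).
#' @param fusion Optional list of [fusion_array()]s; requires `noise`.
#' @param noise Noise estimate from [estimate_noise()] (required with
#'   `fusion`).
#' @param timeframe Analysis time frame in seconds.
#' @param rate Target feature rate in Hz (default 200, chosen to resolve the
#'   fastest activity-generated vibration rate of about 10 Hz).
#' @param levels,wavelet,taper,mode Passed to [mldwt_decompose()].
#' @param pool Pooling rule, see [resample_detail()].
#' @param normalize Per-row normalization: `"maxabs"` (default; divide by
#'   the row's maximum absolute value, all-zero rows left unchanged),
#'   `"zscore"`, or `"none"`.
#' @return A numeric matrix of class `feature_matrix` with attributes
#'   `row_index` (data.frame with `axis`, `level`), `timeframe` and `rate`.
#' @export
build_feature_matrix <- function(seq, axes = c("ax", "ay", "az", "wy"),
                                 fusion = NULL, noise = NULL, timeframe,
                                 rate = 200, levels = 10, wavelet = "coif5",
                                 taper = 0.1,
                                 mode = c("periodization", "symmetric"),
                                 pool = c("absmax", "max"),
                                 normalize = c("maxabs", "zscore", "none")) {
  mode <- match.arg(mode)
  pool <- match.arg(pool)
  normalize <- match.arg(normalize)
  unknown <- setdiff(axes, imu_axes())
  if (length(unknown)) stop("unknown axis: ", paste(unknown, collapse = ", "))
  dur <- imu_duration(seq)
  if (dur < timeframe - 0.5 / seq$sample_rate) {
    stop("section duration ", round(dur, 4), " s is shorter than timeframe ",
         timeframe, " s")
  }
  if (dur > timeframe + 0.5 / seq$sample_rate) {
    seq <- imu_section(seq, seq$start_time, timeframe)
  }
  if (is.null(fusion)) {
    ds <- decompose_section(seq, axes, levels = levels, wavelet = wavelet,
                            taper = taper, mode = mode)
  } else {
    ds <- apply_fusion(seq, fusion, noise, axes = axes, levels = levels,
                       wavelet = wavelet, taper = taper, mode = mode)
  }
  M <- as.integer(round(rate * timeframe))
  rows <- vector("list", length(axes) * levels)
  ri_axis <- character(length(rows))
  ri_level <- integer(length(rows))
  i <- 0L
  for (ax in axes) {
    for (k in seq_len(levels)) {
      i <- i + 1L
      v <- resample_detail(ds$details[[ax]][[k]], M, pool = pool)
      if (normalize == "maxabs") {
        mx <- max(abs(v))
        if (mx > 0) v <- v / mx
      } else if (normalize == "zscore") {
        s <- stats::sd(v)
        if (s > 0) v <- (v - mean(v)) / s
      }
      rows[[i]] <- v
      ri_axis[i] <- ax
      ri_level[i] <- k
    }
  }
  fm <- do.call(rbind, rows)
  structure(fm,
            row_index = data.frame(axis = ri_axis, level = ri_level),
            timeframe = timeframe, rate = rate,
            class = c("feature_matrix", class(fm)))
}

#' Decompose several axes of an IMU section
#'
#' @param seq An [imu_sequence()].
#' @param axes Axes to decompose.
#' @inheritParams build_feature_matrix
#' @return A list of class `detail_set`: `details` is a named list mapping
#'   each axis to its list of level-1..`levels` detail vectors;
#'   `approximations` holds the discarded final approximation per axis.
#' @export
decompose_section <- function(seq, axes = c("ax", "ay", "az", "wy"),
                              levels = 10, wavelet = "coif5", taper = 0.1,
                              mode = c("periodization", "symmetric")) {
  mode <- match.arg(mode)
  details <- approx <- stats::setNames(vector("list", length(axes)), axes)
  for (ax in axes) {
    dec <- mldwt_decompose(seq$data[, ax], levels = levels, wavelet = wavelet,
                           taper = taper, mode = mode,
                           sample_rate = seq$sample_rate)
    details[[ax]] <- dec$details
    approx[[ax]] <- dec$approximation
  }
  structure(list(details = details, approximations = approx, levels = levels,
                 wavelet = wavelet, taper = taper, mode = mode,
                 sample_rate = seq$sample_rate, fused = character(0)),
            class = "detail_set")
}
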