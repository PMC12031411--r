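# Multi-level discrete wavelet decomposition (Mallat algorithm).
#
# Orthonormal coif5 analysis bank. The default boundary mode is periodization,
# which keeps level-k coefficient counts at exactly ceiling(N/2^k) and makes
# the transform exactly orthonormal (coefficient energy equals signal energy).
# A symmetric (half-point mirror) mode is available for comparison; it carries
# boundary-extension slack in both length and energy.

# coif5 decomposition filters (orthonormal Coiflet, 5 vanishing moments,
# 30 taps; low-pass followed by the quadrature mirror high-pass)
coif5_dec_lo <- c(
  -9.6040101127678941e-08, -1.6237995172048338e-07, 2.0612203985788783e-06,
  3.7007277113394796e-06, -2.1270221672515614e-05, -4.1219861924265501e-05,
  1.4035632812373243e-04, 3.0185794166824478e-04, -6.3755892612588115e-04,
  -1.6616273039298788e-03, 2.4315754425382886e-03, 6.7615202206204169e-03,
  -9.1595073386761625e-03, -1.9758391600965465e-02, 3.2674799467057355e-02,
  4.1287530472117834e-02, -1.0556315130733723e-01, -6.2037751574981960e-02,
  4.3798230665916338e-01, 7.7429362286032744e-01, 4.2157126673075435e-01,
  -5.2046670253554764e-02, -9.1921588060086087e-02, 2.8169744270532353e-02,
  2.3408322118927783e-02, -1.0131584846900276e-02, -4.1593126275786402e-03,
  2.1782943778456947e-03, 3.5857774116175768e-04, -2.1208186206749400e-04
)

wavelet_filters <- function(wavelet = "coif5") {
  if (!identical(wavelet, "coif5")) {
    stop("only the 'coif5' wavelet is provided")
  }
  lo <- coif5_dec_lo
  n <- length(lo)
  # quadrature mirror: hi[k] = (-1)^(k+1) * lo[n - 1 - k] (0-based)
  hi <- rev(lo) * (-1)^seq_len(n)
  list(lo = lo, hi = hi, length = n)
}

#' Tukey (tapered cosine) window
#'
#' @param n Window length in samples.
#' @param alpha Fraction of the window inside the two cosine tapers
#'   (0 = rectangular, 1 = Hann). Default 0.1.
#' @return Numeric vector of length `n`.
#' @export
tukey_window <- function(n, alpha = 0.1) {
  stopifnot(n >= 1, alpha >= 0, alpha <= 1)
  if (n == 1L || alpha == 0) return(rep(1, n))
  u <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  lo <- u < alpha / 2
  hi <- u > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * u[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * u[hi] / alpha - 2 / alpha + 1)))
  w
}

# one analysis step: returns list(a = approximation, d = detail)
dwt_step <- function(x, filters, mode = c("periodization", "symmetric")) {
  mode <- match.arg(mode)
  L <- filters$length
  n <- length(x)
  if (mode == "periodization") {
    if (n %% 2L == 1L) { x <- c(x, x[n]); n <- n + 1L }
    # circular convolution evaluated at even phases, with the filter group
    # delay (L/2) compensated so coefficients stay time-aligned with the
    # signal: y[k] = sum_m f[m] * x[(2(k-1) + L/2 - (m-1)) mod n]
    step <- .dwt_step_per(x, filters$lo, filters$hi)
    a <- step$a
    d <- step$d
  } else {
    # half-point symmetric extension, full convolution, even-phase subsample
    ext <- c(x[pmin(L - 1L, n):1L], x, x[n:pmax(1L, n - L + 1L)])
    conv_lo <- stats::filter(ext, filters$lo, method = "convolution",
                             sides = 1)
    conv_hi <- stats::filter(ext, filters$hi, method = "convolution",
                             sides = 1)
    pos <- seq(L, length(ext), by = 1L)      # valid part
    keep <- seq(2L, n + L - 2L, by = 2L)
    a <- as.numeric(conv_lo[L - 1L + keep])
    d <- as.numeric(conv_hi[L - 1L + keep])
  }
  list(a = a, d = d)
}

#' Multi-level discrete wavelet decomposition of one axis
#'
#' Applies a Tukey taper to the time-domain signal and recursively splits the
#' approximation band, collecting the detail (band-pass) coefficients of
#' levels 1..`levels`. Level k spans roughly `fs/2^(k+1)` to `fs/2^k` Hz; at
#' 7 kHz and 10 levels the coarsest retained band reaches down to about
#' 6.8 Hz and the final approximation (everything below it) is discarded from
#' the feature set, though it is returned for diagnostics.
#'
#' @param signal Numeric vector, one sensor axis.
#' @param levels Number of decomposition levels (default 10).
#' @param wavelet Wavelet name; `"coif5"`.
#' @param taper Tukey taper fraction applied to the whole signal before
#'   decomposition (default 0.1); `0` disables windowing.
#' @param mode Boundary handling: `"periodization"` (default, exactly
#'   orthonormal) or `"symmetric"`.
#' @param sample_rate Sampling rate of `signal` in Hz, stored for band
#'   bookkeeping.
#' @return A list of class `mldwt` with elements `details` (list of `levels`
#'   coefficient vectors, finest first), `approximation`, `levels`,
#'   `wavelet`, `mode` and `sample_rate`.
#' @export
mldwt_decompose <- function(signal, levels = 10, wavelet = "coif5",
                            taper = 0.1, mode = c("periodization", "symmetric"),
                            sample_rate = 7000) {
  mode <- match.arg(mode)
  n <- length(signal)
  if (n < 2^levels) {
    stop("signal too short for ", levels, "-level decomposition: need at ",
         "least ", 2^levels, " samples, got ", n)
  }
  filters <- wavelet_filters(wavelet)
  x <- signal * tukey_window(n, taper)
  details <- vector("list", levels)
  for (k in seq_len(levels)) {
    step <- dwt_step(x, filters, mode)
    details[[k]] <- step$d
    x <- step$a
  }
  structure(
    list(details = details, approximation = x, levels = levels,
         wavelet = wavelet, mode = mode, taper = taper,
         sample_rate = sample_rate),
    class = "mldwt"
  )
}

#' Dyadic band of a decomposition level, and the level containing a frequency
#'
#' Level k of an `fs`-sampled decomposition spans `fs/2^(k+1)` to `fs/2^k`
#' Hz. `level_for_frequency()` returns the level whose band contains `f`,
#' warning when `f` lies within 10% of a band edge (band leakage makes the
#' mapping unreliable there).
#'
#' @param level Decomposition level (1 = finest).
#' @param f Frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param levels Total number of levels available.
#' @return `level_band()`: numeric `c(lower, upper)` in Hz;
#'   `level_for_frequency()`: integer level.
#' @export
level_band <- function(level, fs) c(fs / 2^(level + 1), fs / 2^level)

#' @rdname level_band
#' @export
level_for_frequency <- function(f, fs, levels = 10) {
  stopifnot(f > 0, f < fs / 2)
  k <- floor(log2(fs / f))
  if (k < 1 || k > levels) {
    stop("frequency ", f, " Hz maps to level ", k,
         ", outside the decomposed range 1..", levels)
  }
  band <- level_band(k, fs)
  rel <- min(f - band[1], band[2] - f) / (band[2] - band[1])
  if (rel < 0.1) {
    warning(sprintf(
      "mode frequency %g Hz lies near a dyadic band edge (level %d band %.1f-%.1f Hz); consider an explicit level override",
      f, k, band[1], band[2]))
  }
  as.integer(k)
}
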