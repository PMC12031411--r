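# Shared fixtures and independent oracles for the test suite.

# short sequence fixture: deterministic two-tone + noise
make_test_imu <- function(n = 7000, fs = 7000, seed = 1) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  base <- sin(2 * pi * 94 * t) * 1e-3
  data <- cbind(ax = base * 0.2 + rnorm(n, 0, 1e-4),
                ay = sin(2 * pi * 906 * t) * 5e-4 + rnorm(n, 0, 1e-4),
                az = base + rnorm(n, 0, 1e-4),
                wx = rnorm(n, 0, 1e-5),
                wy = rnorm(n, 0, 1e-5),
                wz = rnorm(n, 0, 1e-5))
  imu_sequence(data, sample_rate = fs)
}

# single-mode noise-free beam, for coupling checks
single_mode_beam <- function(frequency = 94, gain = 0.039688,
                             primary = "az", donor = "wx",
                             phase = pi / 2, fs = 7000) {
  gains <- stats::setNames(rep(0, 6), c("ax", "ay", "az", "wx", "wy", "wz"))
  phases <- gains
  gains[primary] <- 1
  gains[donor] <- gain
  phases[donor] <- phase
  beam_model(modes = list(list(frequency = frequency, damping_ratio = 0.02,
                               gains = unname(gains),
                               phases = unname(phases))),
             noise_sd = rep(0, 6), sample_rate = fs)
}

# brute-force per-block pooling oracle (independent of resample_detail)
pool_oracle <- function(x, M, pool = "absmax") {
  N <- length(x)
  if (M >= N) {
    out <- numeric(M)
    for (n in seq_len(N)) {
      lo <- floor((n - 1) * M / N) + 1
      hi <- floor(n * M / N)
      out[lo:hi] <- x[n]
    }
    return(out)
  }
  out <- numeric(M)
  for (m in seq_len(M)) {
    blk <- x[(floor((m - 1) * N / M) + 1):floor(m * N / M)]
    out[m] <- if (pool == "max") max(blk) else blk[which.max(abs(blk))]
  }
  out
}

# brute-force periodized analysis step (circular convolution, direct sums)
dwt_oracle <- function(x, lo, hi) {
  n <- length(x)
  if (n %% 2 == 1) { x <- c(x, x[n]); n <- n + 1 }
  L <- length(lo)
  a <- d <- numeric(n / 2)
  for (k in seq_len(n / 2)) {
    idx <- ((2 * (k - 1) + L %/% 2 - (seq_len(L) - 1)) %% n) + 1
    a[k] <- sum(lo * x[idx])
    d[k] <- sum(hi * x[idx])
  }
  list(a = a, d = d)
}
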