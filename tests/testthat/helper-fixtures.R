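# Shared fixtures: tiny recordings and signal builders, all generated in code.

identity_calib <- function(...) sensor_calibration(...)

# a recording from explicit anatomical-frame signals (identity calibration)
make_recording <- function(acc = matrix(0, 3, 100), gyr = matrix(0, 3, 100),
                           id = "r1", event = "e1", ts = 0, ir = 200) {
  recording(id, event, ts, acc, gyr, ir)
}

# half-sine acceleration pulse along one axis, amplitude in g, duration s
half_sine_acc <- function(axis, amp, dur_s, start_s = 0.010) {
  t <- (0:99) * 1e-3
  acc <- matrix(0, 3, 100)
  acc[axis, ] <- ifelse(t >= start_s & t <= start_s + dur_s,
                        amp * sin(pi * (t - start_s) / dur_s), 0)
  acc
}

tone3 <- function(axis, amp, freq, fs = 1000, n = 100) {
  m <- matrix(0, 3, n)
  m[axis, ] <- amp * sin(2 * pi * freq * (0:(n - 1)) / fs)
  m
}

random_rotation <- function() {
  A <- matrix(stats::rnorm(9), 3)
  qr_ <- qr(A)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

zero_signals <- function() {
  preprocess_recording(make_recording(), identity_calib())
}

# Full-enumeration oracle for the exact two-sided rank-sum p-value
ranksum_enumeration <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  combos <- utils::combn(length(pooled), n1)
  W_obs <- sum(rank(pooled)[seq_len(n1)])
  Ws <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

# Brute-force one-sided DFT-sum periodogram, independent of the fft path
psd_oracle <- function(x, fs = 1000) {
  n <- length(x)
  k <- 0:(n / 2)
  vapply(k, function(kk) {
    re <- sum(x * cos(-2 * pi * kk * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * kk * (0:(n - 1)) / n))
    p <- (re^2 + im^2) / (fs * n)
    if (kk > 0 && kk < n / 2) 2 * p else p
  }, 0)
}
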