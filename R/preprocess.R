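#' Rotate a triaxial series into the head anatomical frame
#'
#' Applies the calibration rotation to every sample of a 3 x N series.
#' Per-sample Euclidean norms are preserved exactly (up to floating point).
#'
#' @param triad 3 x N numeric matrix (device frame).
#' @param R 3 x 3 rotation matrix, device to anatomical.
#' @return 3 x N matrix in the anatomical frame.
#' @export
rotate_to_anatomical <- function(triad, R) {
  check_rotation(R)
  stopifnot(is.matrix(triad), nrow(triad) == 3)
  R %*% triad
}

#' Zero-phase low-pass Butterworth filter
#'
#' Fourth-order Butterworth design applied forward and backward
#' (`signal::filtfilt`), i.e. phaseless filtering in the SAE J211 spirit;
#' the forward-backward pass doubles the effective order. A cutoff at or
#' within 1% of Nyquist is a degenerate design and the series is passed
#' through unchanged (this is the accelerometer case: 500 Hz bandwidth at a
#' 1000 Hz sampling rate).
#'
#' @param series Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param cutoff Low-pass cutoff in Hz (> 0).
#' @param order Filter order before the forward-backward doubling; default 4.
#' @return Filtered series, same length.
#' @export
lowpass_butterworth <- function(series, fs = FS_HZ, cutoff, order = 4) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0)
    stop("parameter error: cutoff must be a positive scalar", call. = FALSE)
  if (cutoff >= 0.99 * fs / 2) return(series)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  filtfilt_padded(bf$b, bf$a, series)
}

# Zero-phase filtering with odd-reflection padding and steady-state initial
# conditions, so a constant series is reproduced exactly and edge transients
# stay out of the 100 ms window. (signal::filtfilt starts from zero states,
# which distorts the window edges at this short record length.)
filtfilt_padded <- function(b, a, x) {
  n <- length(x)
  padlen <- min(n - 1, 3 * (max(length(a), length(b)) - 1) * 3)
  xp <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- lfilter_zi(b, a)
  fwd <- lfilter(b, a, xp, zi * xp[1])
  rev_in <- rev(fwd)
  bwd <- lfilter(b, a, rev_in, zi * rev_in[1])
  y <- rev(bwd)
  y[(padlen + 1):(padlen + n)]
}

# direct-form II transposed IIR filter with initial state
lfilter <- function(b, a, x, zi) {
  m <- max(length(a), length(b)) - 1
  b <- c(b, rep(0, m + 1 - length(b)))
  a <- c(a, rep(0, m + 1 - length(a)))
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    if (m > 1) {
      z[1:(m - 1)] <- b[2:m] * x[i] + z[2:m] - a[2:m] * y[i]
    }
    z[m] <- b[m + 1] * x[i] - a[m + 1] * y[i]
  }
  y
}

# steady-state filter state for unit DC input (lfilter_zi analogue):
# solve (I - A) zi = B with the companion-form state update
lfilter_zi <- function(b, a) {
  m <- max(length(a), length(b)) - 1
  b <- c(b, rep(0, m + 1 - length(b)))
  a <- c(a, rep(0, m + 1 - length(a)))
  IminusA <- diag(m)
  IminusA[, 1] <- IminusA[, 1] + a[2:(m + 1)]
  if (m > 1)
    for (i in seq_len(m - 1)) IminusA[i, i + 1] <- IminusA[i, i + 1] - 1
  B <- b[2:(m + 1)] - a[2:(m + 1)] * b[1]
  as.numeric(solve(IminusA, B))
}

#' Cumulative trapezoid integration
#'
#' `out[1] = 0`; `out[k]` is the trapezoid-rule integral over samples
#' `1..k` on a uniform grid with spacing `dt`. Exact for piecewise-linear
#' integrands.
#'
#' @param series Numeric vector, finite.
#' @param dt Sample spacing in seconds.
#' @return Numeric vector, same length.
#' @export
cumulative_trapezoid_integral <- function(series, dt = DT_S) {
  stopifnot(all(is.finite(series)))
  if (length(series) == 1) return(0)
  as.numeric(pracma::cumtrapz(seq_along(series) * dt, series))
}

#' Five-point-stencil derivative
#'
#' Interior samples use the central five-point stencil
#' `(-f(t+2h) + 8 f(t+h) - 8 f(t-h) + f(t-2h)) / (12 h)`, exact for
#' polynomials up to degree 4. The first/last two samples fall back to
#' progressively lower-order one-sided differences (4-point one-sided at
#' indices 2 and N-1, 2-point forward/backward at the ends) so the output
#' keeps the input length without padding artifacts.
#'
#' @param series Numeric vector, length >= 5.
#' @param dt Sample spacing in seconds.
#' @return Numeric vector of derivatives, same length.
#' @export
five_point_derivative <- function(series, dt = DT_S) {
  n <- length(series)
  if (n < 5)
    stop("length error: five-point stencil needs at least 5 samples",
         call. = FALSE)
  f <- series
  d <- numeric(n)
  i <- 3:(n - 2)
  d[i] <- (-f[i + 2] + 8 * f[i + 1] - 8 * f[i - 1] + f[i - 2]) / (12 * dt)
  d[2] <- (-2 * f[1] - 3 * f[2] + 6 * f[3] - f[4]) / (6 * dt)
  d[n - 1] <- (2 * f[n] + 3 * f[n - 1] - 6 * f[n - 2] + f[n - 3]) / (6 * dt)
  d[1] <- (f[2] - f[1]) / dt
  d[n] <- (f[n] - f[n - 1]) / dt
  d
}

GRAVITY_MS2 <- 9.80665

#' Preprocess a recording into anatomical-frame derived signals
#'
#' The full chain every feature is computed from, in order: rotate the
#' device-frame triads to the anatomical frame; low-pass filter each channel
#' at its sensor bandwidth (accelerometer 500 Hz -- a passthrough at this
#' sampling rate -- and gyroscope 184 Hz); integrate linear acceleration
#' (converted g to m/s^2, zero initial velocity, no gravity subtraction --
#' the 100 ms triggered window does not resolve the gravity vector) to
#' linear velocity; differentiate angular velocity with the five-point
#' stencil to angular acceleration; and compute the vector magnitude of
#' each quantity. Linear acceleration is deliberately *not* transformed to
#' the head centre of gravity here, to avoid cross-coupling linear and
#' angular features; the linkage-model features do their own transform.
#'
#' @param rec A [recording()].
#' @param calib A [sensor_calibration()].
#' @return Object of class `anatomical_signals`: matrices `lin_acc` (g),
#'   `lin_vel` (m/s), `ang_vel` (rad/s), `ang_acc` (rad/s^2), each 3 x 100
#'   with rows AP/LR/IS (linear) or coronal/sagittal/horizontal (angular);
#'   magnitude vectors `lin_acc_mag`, `lin_vel_mag`, `ang_vel_mag`,
#'   `ang_acc_mag`; `dt`; and `time_s` (window clock, trigger at 10 ms).
#' @export
preprocess_recording <- function(rec, calib) {
  validate_recording(rec)
  stopifnot(inherits(calib, "sensor_calibration"))
  la <- rotate_to_anatomical(rec$lin_acc_device, calib$device_to_anatomical)
  av <- rotate_to_anatomical(rec$ang_vel_device, calib$device_to_anatomical)
  la <- t(apply(la, 1, lowpass_butterworth, fs = FS_HZ,
                cutoff = calib$accel_cutoff))
  av <- t(apply(av, 1, lowpass_butterworth, fs = FS_HZ,
                cutoff = calib$gyro_cutoff))
  lv <- t(apply(la * GRAVITY_MS2, 1, cumulative_trapezoid_integral, dt = DT_S))
  aa <- t(apply(av, 1, five_point_derivative, dt = DT_S))
  dimnames(la) <- dimnames(lv) <- list(c("ap", "lr", "is"), NULL)
  dimnames(av) <- dimnames(aa) <- list(c("cor", "sag", "hor"), NULL)
  structure(list(
    lin_acc = la, lin_vel = lv, ang_vel = av, ang_acc = aa,
    lin_acc_mag = sqrt(colSums(la^2)), lin_vel_mag = sqrt(colSums(lv^2)),
    ang_vel_mag = sqrt(colSums(av^2)), ang_acc_mag = sqrt(colSums(aa^2)),
    dt = DT_S, time_s = (seq_len(N_SAMPLES) - 1) * DT_S
  ), class = "anatomical_signals")
}
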