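#' Full-width-at-half-maximum impulse duration
#'
#' Width of the dominant impulse at half its maximum value: from the first
#' sub-half-maximum sample left of the global peak to the first right of it,
#' with linear sub-sample interpolation of the crossing times. When the
#' series never falls below half-maximum on a side, that side clamps to the
#' window edge. An all-zero (or all-equal-zero) series returns duration 0
#' with attribute `degenerate = TRUE`.
#'
#' @param series Nonnegative numeric vector (a magnitude or rectified
#'   component series).
#' @param dt Sample spacing in seconds.
#' @return Duration in seconds.
#' @export
fwhm_duration <- function(series, dt = DT_S) {
  stopifnot(all(series >= 0))
  n <- length(series)
  pk <- which.max(series)
  half <- series[pk] / 2
  if (half <= 0) return(structure(0, degenerate = TRUE))
  cross <- function(i_out, i_in) {
    # linear interpolation between a sub-half sample and its in-pulse neighbour
    i_out + (half - series[i_out]) / (series[i_in] - series[i_out]) *
      (i_in - i_out)
  }
  left <- 1
  if (pk > 1) for (i in rev(seq_len(pk - 1))) {
    if (series[i] < half) { left <- cross(i, i + 1); break }
  }
  right <- n
  if (pk < n) for (i in (pk + 1):n) {
    if (series[i] < half) { right <- cross(i, i - 1); break }
  }
  (right - left) * dt
}

#' Time-domain feature block (24 features)
#'
#' Peak kinematics and impulse durations: maxima of linear acceleration,
#' change in linear velocity, angular acceleration, and change in angular
#' velocity, in each anatomical component and in vector magnitude
#' (16 features), plus half-maximum impulse durations of linear and angular
#' acceleration per component and magnitude (8 features). Directional peaks
#' use the absolute value so left- and right-going impacts score equally;
#' directional "change in" is max minus min over the window, and for the
#' magnitude series (which starts at zero for the integrated velocity) the
#' change is its maximum.
#'
#' @param sig An `anatomical_signals` object from [preprocess_recording()].
#' @return Named numeric vector of 24 features (units: g, m/s, rad/s^2,
#'   rad/s, seconds).
#' @export
time_domain_features <- function(sig) {
  peak_abs <- function(m) apply(abs(m), 1, max)
  delta <- function(m) apply(m, 1, max) - apply(m, 1, min)
  fw <- function(m, mag) {
    c(apply(abs(m), 1, function(s) as.numeric(fwhm_duration(s, sig$dt))),
      as.numeric(fwhm_duration(mag, sig$dt)))
  }
  out <- c(
    c(peak_abs(sig$lin_acc), max(sig$lin_acc_mag)),
    c(delta(sig$lin_vel), max(sig$lin_vel_mag)),
    c(peak_abs(sig$ang_acc), max(sig$ang_acc_mag)),
    c(delta(sig$ang_vel), max(sig$ang_vel_mag)),
    fw(sig$lin_acc, sig$lin_acc_mag),
    fw(sig$ang_acc, sig$ang_acc_mag)
  )
  reg <- feature_registry()
  stats::setNames(out, reg[seq_len(24)])
}

#' One-sided rectangular-window periodogram
#'
#' Raw periodogram of a length-100 series at 1000 Hz, without detrending or
#' tapering: with this window the DFT bins land exactly on multiples of
#' 10 Hz, which is what makes "PSD at 10--200 Hz in 10 Hz intervals" well
#' defined with no interpolation. One-sided power density scaling
#' (`|X[k]|^2 / (fs * N)`, doubled for interior bins) so that the sum of
#' PSD times the 10 Hz bin width equals the mean square of the series
#' (Parseval). The 100-sample window is part of the method: other lengths
#' are a length error, not a zero-pad.
#'
#' @param series Numeric vector of length 100.
#' @param fs Sampling rate, 1000 Hz.
#' @return Named numeric vector of PSD values at 0, 10, ..., 500 Hz, with
#'   attribute `freq`.
#' @export
periodogram_psd <- function(series, fs = FS_HZ) {
  n <- length(series)
  if (n != N_SAMPLES)
    stop(sprintf("length error: periodogram requires exactly 100 samples (got %d)", n),
         call. = FALSE)
  X <- stats::fft(series)
  p2 <- Mod(X)^2 / (fs * n)
  k <- 0:(n / 2)
  p1 <- p2[k + 1]
  p1[2:(n / 2)] <- 2 * p1[2:(n / 2)]
  freq <- k * fs / n
  structure(stats::setNames(p1, sprintf("%ghz", freq)), freq = freq)
}

#' Power-spectral-density feature block (152 features)
#'
#' Periodogram power of linear acceleration at 10--200 Hz and of angular
#' acceleration at 10--180 Hz, in 10 Hz intervals, for each anatomical
#' component and the vector magnitude: 4 x 20 + 4 x 18 = 152 values. The
#' 180 Hz ceiling for angular signals reflects the gyroscope's 184 Hz
#' bandwidth; 200 Hz for linear signals keeps roughly six samples per
#' period at the 1000 Hz sampling rate.
#'
#' @param sig An `anatomical_signals` object.
#' @return Named numeric vector of 152 PSD features.
#' @export
psd_features <- function(sig) {
  lin <- rbind(sig$lin_acc, mag = sig$lin_acc_mag)
  ang <- rbind(sig$ang_acc, mag = sig$ang_acc_mag)
  vals <- c(
    unlist(lapply(seq_len(4), function(i)
      periodogram_psd(lin[i, ])[2:21])),      # 10..200 Hz
    unlist(lapply(seq_len(4), function(i)
      periodogram_psd(ang[i, ])[2:19]))       # 10..180 Hz
  )
  reg <- feature_registry()
  stats::setNames(as.numeric(vals), reg[24 + seq_len(152)])
}

#' Continuous Morlet wavelet scalogram
#'
#' Amplitude of the continuous wavelet transform with the analytic Morlet
#' mother wavelet (centre frequency `omega0 = 6`), evaluated on a 10 Hz
#' frequency grid. The transform is computed by direct time-domain
#' convolution with L2-normalized, time-reversed conjugate wavelets whose
#' support is truncated at the window edges (no cone-of-influence masking:
#' the window is only 100 ms). Scale for frequency f uses the standard
#' Fourier-factor conversion for the Morlet family.
#'
#' @param series Numeric vector of length 100.
#' @param fs Sampling rate in Hz.
#' @param freqs Analysis frequencies in Hz, ascending; all below `fs/2`.
#' @param omega0 Morlet nondimensional centre frequency (default 6).
#' @return Object of class `scalogram`: list with `freq` (Hz), `time_s`,
#'   and `amplitude` (length(freqs) x length(series), >= 0).
#' @export
morlet_scalogram <- function(series, fs = FS_HZ,
                             freqs = seq(10, 200, by = 10), omega0 = 6) {
  if (any(freqs >= fs / 2) || any(freqs <= 0))
    stop("parameter error: analysis frequencies must lie in (0, fs/2)",
         call. = FALSE)
  n <- length(series)
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  amp <- matrix(0, length(freqs), n)
  diffs <- outer(seq_len(n), seq_len(n), function(t0, u) u - t0) # u - t
  for (j in seq_along(freqs)) {
    scale <- 1 / (freqs[j] * fourier_factor)      # seconds
    s_samp <- scale * fs
    eta <- (-(n - 1)):(n - 1) / s_samp
    psi <- pi^(-0.25) * exp(1i * omega0 * eta) * exp(-eta^2 / 2) / sqrt(s_samp)
    psi[abs(eta) > 4] <- 0
    # W[t] = sum_u x[u] Conj(psi((u - t)/s)), kernel truncated at |eta| > 4
    K <- matrix(Conj(psi[diffs + n]), n, n)
    amp[j, ] <- Mod(as.vector(K %*% series))
  }
  structure(list(freq = freqs, time_s = (seq_len(n) - 1) / fs,
                 amplitude = amp), class = "scalogram")
}

wt_channel_descriptors <- function(scal, td_peak_time) {
  amp <- scal$amplitude
  gmax <- max(amp)
  if (gmax <= 0)
    return(structure(c(0, scal$freq[1], 0, 0), degenerate = TRUE))
  idx <- which(amp == gmax, arr.ind = TRUE)[1, ]
  f_peak <- scal$freq[idx[1]]
  t_peak <- scal$time_s[idx[2]]
  timemax <- apply(amp, 1, max)
  above <- which(scal$freq >= f_peak & timemax < 0.1 * gmax)
  bw <- if (length(above)) scal$freq[above[1]] - f_peak else
    scal$freq[length(scal$freq)] - f_peak
  c(gmax, f_peak, t_peak - td_peak_time, bw)
}

#' Wavelet feature block (184 features)
#'
#' Morlet wavelet features of linear acceleration (grid 10--200 Hz) and
#' angular acceleration (10--180 Hz) per component and magnitude. Two
#' sub-blocks: the per-frequency maxima over time of the wavelet amplitude
#' (152 features, mirroring the PSD grid but time-localized), and four
#' descriptors per channel (32 features): global peak amplitude, its
#' frequency, its timing relative to the channel's time-domain peak, and
#' the 10% bandwidth -- the distance from the peak frequency up to the first
#' grid frequency whose time-maximal amplitude drops below 10% of the
#' global maximum (capped at the grid ceiling). A zero channel yields
#' degenerate descriptors (0, lowest grid frequency, 0, 0).
#'
#' @param sig An `anatomical_signals` object.
#' @return Named numeric vector of 184 features (152 per-frequency + 32
#'   descriptors) in registry order.
#' @export
wavelet_features <- function(sig) {
  lin <- rbind(sig$lin_acc, mag = sig$lin_acc_mag)
  ang <- rbind(sig$ang_acc, mag = sig$ang_acc_mag)
  lin_f <- seq(10, 200, by = 10)
  ang_f <- seq(10, 180, by = 10)
  perfreq <- c()
  descs <- c()
  for (set in list(list(m = lin, f = lin_f), list(m = ang, f = ang_f))) {
    for (i in seq_len(4)) {
      ch <- set$m[i, ]
      scal <- morlet_scalogram(ch, FS_HZ, set$f)
      perfreq <- c(perfreq, apply(scal$amplitude, 1, max))
      td_series <- if (i == 4) ch else abs(ch)
      td_peak_time <- sig$time_s[which.max(td_series)]
      descs <- c(descs, as.numeric(wt_channel_descriptors(scal, td_peak_time)))
    }
  }
  # registry order: all per-frequency features first, then all descriptors
  reg <- feature_registry()
  stats::setNames(c(perfreq, descs), reg[176 + seq_len(184)])
}

#' Assemble the canonical 411-feature vector
#'
#' Concatenates the block outputs in canonical registry order and validates
#' sizes and names. Any missing or over-sized block is a registry error
#' naming the offending block.
#'
#' @param time24 Output of [time_domain_features()].
#' @param psd152 Output of [psd_features()].
#' @param wt184 Output of [wavelet_features()].
#' @param model51 Output of [neck_model_features()].
#' @return Named numeric vector of exactly 411 features.
#' @export
assemble_feature_vector <- function(time24, psd152, wt184, model51) {
  sizes <- c(time24 = 24L, psd152 = 152L, wt184 = 184L, model51 = 51L)
  blocks <- list(time24 = time24, psd152 = psd152, wt184 = wt184,
                 model51 = model51)
  for (b in names(sizes)) {
    if (length(blocks[[b]]) != sizes[[b]])
      stop(sprintf("registry error: block '%s' has %d features, expected %d",
                   b, length(blocks[[b]]), sizes[[b]]), call. = FALSE)
  }
  v <- c(time24, psd152, wt184, model51)
  reg <- feature_registry()
  if (!identical(names(v), as.character(reg)))
    stop("registry error: assembled names do not match the canonical registry",
         call. = FALSE)
  v
}

#' Extract the full 411-feature vector from one recording
#'
#' Runs [preprocess_recording()] and all four feature blocks, returning the
#' canonical feature vector. This is the per-recording unit of work behind
#' [extract_features()].
#'
#' @param rec A [recording()].
#' @param calib A [sensor_calibration()].
#' @param neck Neck model parameters, see [neck_model_params()].
#' @return Named numeric vector of 411 features.
#' @export
extract_feature_vector <- function(rec, calib, neck = neck_model_params()) {
  sig <- preprocess_recording(rec, calib)
  assemble_feature_vector(
    time_domain_features(sig),
    psd_features(sig),
    wavelet_features(sig),
    neck_model_features_from_signals(sig, neck)
  )
}
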