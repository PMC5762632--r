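#' Synthetic cohort configuration
#'
#' Defaults emulate the documented field phenomenology of triggered
#' instrumented-mouthguard data: 10 g-triggered 100 ms windows; impacts as
#' low-frequency (sub-100 Hz) directional pulses with coherent low-band
#' angular motion and occasional 100--200 Hz helmet/jaw ringing; nonimpacts
#' as brief high-frequency (120--350 Hz) multi-axis damped oscillations
#' from device handling, often with a low-amplitude handling swipe;
#' overlapping peak-amplitude distributions (impacts 10--65 g around a
#' 22 g mean, nonimpacts 10--104 g around an 18.5 g mean, angular-velocity
#' changes 1.6--26 vs 0.1--55.7 rad/s); bimodal IR readings with the
#' on/off-teeth modes separated by six pooled standard deviations; and up
#' to one second of clock skew between video and mouthguard timestamps.
#'
#' @param n_impact,n_nonimpact,n_off_teeth,n_no_view Class counts: video-
#'   verifiable impacts, verifiable nonimpacts, off-teeth recordings, and
#'   impact-like recordings planted inside no-view periods (confounders).
#' @param impact_amp_range,impact_amp_mean_excess Impact peak |linear
#'   acceleration| in g: truncated shifted-exponential draw on the range
#'   with the given mean excess over the trigger floor.
#' @param nonimpact_amp_range,nonimpact_amp_mean_excess Same for
#'   nonimpacts.
#' @param impact_freq_band Impact pulse fundamental band, Hz (via pulse
#'   durations); informational, implied by `impact_duration_range_ms`.
#' @param nonimpact_freq_band Nonimpact oscillation carrier band, Hz.
#' @param impact_duration_range_ms Impact pulse duration range, ms.
#' @param nonimpact_decay_range_ms Nonimpact oscillation decay-time range,
#'   ms.
#' @param impact_dw_range,impact_dw_mean_excess Impact angular-velocity
#'   change in rad/s (truncated shifted exponential).
#' @param nonimpact_dw_range,nonimpact_dw_mean_excess Same for nonimpacts.
#' @param ringing_prob,ringing_freq_band Probability and carrier band (Hz)
#'   of superimposed impact ringing (helmet/mandible dynamics within the
#'   sensor bandwidth).
#' @param swipe_prob,swipe_amp_range,swipe_duration_range_ms Handling-swipe
#'   component of nonimpacts: probability, amplitude range (g), duration
#'   range (ms).
#' @param noise_acc_g,noise_gyro_rps Additive white noise RMS per axis.
#' @param ir_mean_low,ir_mean_high,ir_sd IR mixture modes and common sd.
#' @param clock_skew_s Uniform video/mouthguard clock skew half-width (s).
#' @param seed Integer seed for [generate_cohort()].
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_impact = 60, n_nonimpact = 60, n_off_teeth = 100,
                         n_no_view = 3,
                         impact_amp_range = c(10, 65),
                         impact_amp_mean_excess = 12,
                         nonimpact_amp_range = c(10, 104),
                         nonimpact_amp_mean_excess = 8.5,
                         impact_freq_band = c(20, 80),
                         nonimpact_freq_band = c(120, 350),
                         impact_duration_range_ms = c(8, 30),
                         nonimpact_decay_range_ms = c(2, 25),
                         impact_dw_range = c(1.6, 26),
                         impact_dw_mean_excess = 9,
                         nonimpact_dw_range = c(0.1, 55),
                         nonimpact_dw_mean_excess = 5,
                         ringing_prob = 0.5,
                         ringing_freq_band = c(100, 200),
                         swipe_prob = 0.7,
                         swipe_amp_range = c(0.3, 2.5),
                         swipe_duration_range_ms = c(30, 80),
                         noise_acc_g = 0.5, noise_gyro_rps = 0.2,
                         ir_mean_low = 100, ir_mean_high = 160, ir_sd = 10,
                         clock_skew_s = 1, seed = 1L) {
  cfg <- as.list(environment())
  for (nm in grep("range|band", names(cfg), value = TRUE))
    stopifnot(length(cfg[[nm]]) == 2, cfg[[nm]][1] <= cfg[[nm]][2])
  stopifnot(n_impact >= 0, n_nonimpact >= 0, n_off_teeth >= 0, n_no_view >= 0)
  structure(cfg, class = "synth_config")
}

# shifted exponential truncated to [range[1], range[2]]
rtrunc_shiftexp <- function(n, range, mean_excess) {
  x <- range[1] + stats::rexp(n, rate = 1 / mean_excess)
  pmin(x, range[2])
}

rand_unit3 <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# unit vector within `max_angle` of u
jitter_in_cone <- function(u, max_angle) {
  th <- stats::runif(1, 0, max_angle)
  p <- rand_unit3()
  p <- p - sum(p * u) * u
  np <- sqrt(sum(p^2))
  if (np < 1e-9) return(u)
  p <- p / np
  cos(th) * u + sin(th) * p
}

IMPACT_PLANE_ROW <- c(frontal = 2L, rear = 2L, left = 1L, right = 1L,
                      top = 3L)  # coronal = 1, sagittal = 2, horizontal = 3

#' Generate one synthetic triggered recording
#'
#' Draws one recording of the requested class using the current RNG state
#' (or a caller seed). Impacts are direction-consistent half-sine pulses
#' with coherent low-band angular velocity and optional in-band ringing;
#' nonimpacts are multi-axis high-frequency damped oscillation bursts with
#' an optional low-amplitude handling swipe; off-teeth recordings reuse the
#' nonimpact signal model with a low-mode IR draw.
#'
#' @param class_label One of `"impact"`, `"nonimpact"`, `"off_teeth"`.
#' @param cfg A [synth_config()].
#' @param recording_id,subject_event_id,trigger_timestamp Identity fields.
#' @param direction Impact direction; `NULL` samples one uniformly.
#' @param seed Optional integer seed for a reproducible single draw.
#' @return A [recording()] with attribute `truth` (list: class, direction,
#'   planted peak amplitude, planted angular-velocity change).
#' @export
generate_recording <- function(class_label = c("impact", "nonimpact",
                                               "off_teeth"),
                               cfg = synth_config(),
                               recording_id = "r1",
                               subject_event_id = "e1",
                               trigger_timestamp = 0,
                               direction = NULL, seed = NULL) {
  class_label <- match.arg(class_label)
  if (!is.null(seed)) set.seed(seed)
  t <- (0:99) * 1e-3
  t0 <- 0.010                       # trigger instant inside the window
  acc <- matrix(stats::rnorm(300, 0, cfg$noise_acc_g), 3, 100)
  gyr <- matrix(stats::rnorm(300, 0, cfg$noise_gyro_rps), 3, 100)

  if (class_label == "impact") {
    if (is.null(direction))
      direction <- sample(names(DIRECTION_SECTORS), 1)
    A <- rtrunc_shiftexp(1, cfg$impact_amp_range, cfg$impact_amp_mean_excess)
    dur <- stats::runif(1, cfg$impact_duration_range_ms[1],
                        cfg$impact_duration_range_ms[2]) / 1000
    # jitter + off-axis fractions are bounded so the planted pulse (and its
    # integral) always stays inside the 45-degree video-direction cone
    u <- jitter_in_cone(DIRECTION_SECTORS[[direction]], pi / 9)
    pulse <- ifelse(t >= t0 & t <= t0 + dur,
                    sin(pi * (t - t0) / dur), 0)
    pulse <- pulse / max(pulse)   # sampled crest exactly at the drawn peak
    acc <- acc + A * (u %o% pulse)
    # off-axis pulse content: oblique contact excites all three axes
    v <- rand_unit3(); v <- v - sum(v * u) * u
    if (sqrt(sum(v^2)) > 1e-9) {
      v <- v / sqrt(sum(v^2))
      acc <- acc + stats::runif(1, 0.1, 0.35) * A * (v %o% pulse)
    }
    W <- rtrunc_shiftexp(1, cfg$impact_dw_range, cfg$impact_dw_mean_excess)
    gpulse <- ifelse(t >= t0 & t <= t0 + dur, sin(pi * (t - t0) / dur), 0)
    gyr[IMPACT_PLANE_ROW[[direction]], ] <-
      gyr[IMPACT_PLANE_ROW[[direction]], ] + W * gpulse
    if (stats::runif(1) < cfg$ringing_prob) {
      # helmet/mandible ringing inside the sensor bands, on both sensors
      fr <- stats::runif(1, cfg$ringing_freq_band[1], cfg$ringing_freq_band[2])
      tau <- stats::runif(1, 0.003, 0.010)
      ring <- ifelse(t >= t0, exp(-(t - t0) / tau) *
                       sin(2 * pi * fr * (t - t0)), 0)
      acc <- acc + stats::runif(1, 0, 0.8) * A * (rand_unit3() %o% ring)
      gyr <- gyr + stats::runif(1, 0, 0.8) * W * (rand_unit3() %o% ring)
    }
    truth <- list(class = "impact", direction = direction, peak_g = A,
                  dw_rps = W)
    ir <- stats::rnorm(1, cfg$ir_mean_high, cfg$ir_sd)
  } else {
    A <- rtrunc_shiftexp(1, cfg$nonimpact_amp_range,
                         cfg$nonimpact_amp_mean_excess)
    # high-frequency damped oscillation bursts (device ringing, chatter)
    n_burst <- sample(1:3, 1)
    osc <- matrix(0, 3, 100)
    starts <- c(t0, sort(stats::runif(n_burst - 1, t0 + 0.01, 0.07)))
    ratios <- c(1, stats::runif(n_burst - 1, 0.2, 0.7))
    for (b in seq_len(n_burst)) {
      f0 <- stats::runif(1, cfg$nonimpact_freq_band[1],
                         cfg$nonimpact_freq_band[2])
      tau <- stats::runif(1, cfg$nonimpact_decay_range_ms[1],
                          cfg$nonimpact_decay_range_ms[2]) / 1000
      w <- rand_unit3()
      ph <- stats::runif(3, 0, 2 * pi)
      env <- ifelse(t >= starts[b], exp(-(t - starts[b]) / tau), 0)
      for (ax in 1:3)
        osc[ax, ] <- osc[ax, ] + ratios[b] * w[ax] * env *
          sin(2 * pi * f0 * (t - starts[b]) + ph[ax])
    }
    opk <- max(sqrt(colSums(osc^2)))
    if (opk > 0) osc <- osc / opk
    # bite/clack micro-impulses: brief unidirectional spikes from teeth or
    # objects hitting the tray, carrying real velocity changes
    bite <- matrix(0, 3, 100)
    if (stats::runif(1) < 0.6) {
      for (b in seq_len(sample(1:3, 1))) {
        bd <- stats::runif(1, 0.002, 0.004)
        bs <- stats::runif(1, 0.005, 0.09 - bd)
        bp <- ifelse(t >= bs & t <= bs + bd, sin(pi * (t - bs) / bd), 0)
        bite <- bite + stats::runif(1, 0.3, 1) * (rand_unit3() %o% bp)
      }
      bpk <- max(sqrt(colSums(bite^2)))
      if (bpk > 0) bite <- bite / bpk
    }
    mix <- stats::runif(1, 0.3, 1) * osc +
      (if (max(abs(bite)) > 0) stats::runif(1, 0.15, 0.5) * bite else 0)
    mpk <- max(sqrt(colSums(mix^2)))
    if (mpk > 0) mix <- mix * (A / mpk)
    acc <- acc + mix
    if (stats::runif(1) < cfg$swipe_prob) {
      samp <- stats::runif(1, cfg$swipe_amp_range[1], cfg$swipe_amp_range[2])
      sdur <- stats::runif(1, cfg$swipe_duration_range_ms[1],
                           cfg$swipe_duration_range_ms[2]) / 1000
      sstart <- stats::runif(1, 0, max(1e-3, 0.099 - sdur))
      sw <- rand_unit3()
      spulse <- ifelse(t >= sstart & t <= sstart + sdur,
                       sin(pi * (t - sstart) / sdur), 0)
      acc <- acc + samp * (sw %o% spulse)
    }
    W <- rtrunc_shiftexp(1, cfg$nonimpact_dw_range,
                         cfg$nonimpact_dw_mean_excess)
    # handling oscillation as the gyroscope records it: band-limited by the
    # 184 Hz sensor bandwidth but still high relative to impact dynamics
    f0g <- stats::runif(1, 60, min(180, cfg$nonimpact_freq_band[2]))
    taug <- stats::runif(1, cfg$nonimpact_decay_range_ms[1],
                         cfg$nonimpact_decay_range_ms[2]) / 1000
    wg <- rand_unit3()
    phg <- stats::runif(3, 0, 2 * pi)
    envg <- ifelse(t >= t0, exp(-(t - t0) / taug), 0)
    gsig <- matrix(0, 3, 100)
    for (ax in 1:3)
      gsig[ax, ] <- wg[ax] * envg * sin(2 * pi * f0g * (t - t0) + phg[ax])
    gpk <- max(sqrt(colSums(gsig^2)))
    if (gpk > 0) gyr <- gyr + gsig * (W / gpk)
    truth <- list(class = class_label, direction = "none", peak_g = A,
                  dw_rps = W)
    ir <- stats::rnorm(1, if (class_label == "off_teeth") cfg$ir_mean_low
                       else cfg$ir_mean_high, cfg$ir_sd)
  }
  rec <- recording(recording_id, subject_event_id, trigger_timestamp,
                   acc, gyr, ir)
  attr(rec, "truth") <- truth
  rec
}

#' Generate a seeded synthetic cohort with video labels and planted truth
#'
#' Schedules recordings on a single event timeline, 40 s apart so the
#' dilated label windows of different recordings never interact. Each
#' impact gets a matching `helmet_contact` interval with its planted
#' direction and a uniform clock skew within the configured half-width;
#' nonimpacts and off-teeth recordings sit strictly inside long
#' `no_contact`/`idle` intervals; no-view confounders are impact-like
#' recordings inside `no_view` intervals, excluded from the ground truth by
#' construction.
#'
#' @param cfg A [synth_config()]; `cfg$seed` seeds all draws.
#' @return List: `recordings` (list of [recording()]), `labels`
#'   (`video_labels`), `truth` (data frame: recording_id, class, direction,
#'   peak_g, dw_rps, ir_reading, expected ground-truth label under the
#'   planted IR mode; see [expected_ground_truth()] for the realized-draw
#'   expectation).
#' @export
generate_cohort <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  specs <- c(rep("impact", cfg$n_impact), rep("nonimpact", cfg$n_nonimpact),
             rep("off_teeth", cfg$n_off_teeth), rep("no_view", cfg$n_no_view))
  recs <- vector("list", length(specs))
  lab <- list()
  truth <- list()
  for (i in seq_along(specs)) {
    kind <- specs[i]
    tc <- 40 * i                                  # event-clock center, s
    skew <- stats::runif(1, -cfg$clock_skew_s, cfg$clock_skew_s)
    ts <- round(tc + skew)
    id <- sprintf("rec%04d", i)
    if (kind == "impact") {
      rec <- generate_recording("impact", cfg, id, "e1", ts)
      d <- attr(rec, "truth")$direction
      lab[[i]] <- data.frame(start = tc - 0.2, end = tc + 0.3,
                             category = "helmet_contact", direction = d)
      expected <- "impact"
    } else if (kind == "no_view") {
      rec <- generate_recording("impact", cfg, id, "e1", ts)
      attr(rec, "truth")$class <- "no_view"
      lab[[i]] <- data.frame(start = tc - 5, end = tc + 5,
                             category = "no_view", direction = "none")
      expected <- "excluded"
    } else {
      rec <- generate_recording(kind, cfg, id, "e1", ts)
      lab[[i]] <- data.frame(start = tc - 10, end = tc + 10,
                             category = sample(c("no_contact", "idle"), 1),
                             direction = "none")
      expected <- if (kind == "nonimpact") "nonimpact" else "excluded"
    }
    recs[[i]] <- rec
    tr <- attr(rec, "truth")
    truth[[i]] <- data.frame(recording_id = id, class = kind,
                             direction = tr$direction, peak_g = tr$peak_g,
                             dw_rps = tr$dw_rps, ir_reading = rec$ir_reading,
                             expected = expected)
  }
  labels <- if (length(lab)) video_labels(do.call(rbind, lab)) else
    video_labels(data.frame(start = numeric(0), end = numeric(0),
                            category = character(0),
                            direction = character(0)))
  list(recordings = recs,
       labels = labels,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame())
}

#' Rule-level expected ground-truth labels for a synthetic cohort
#'
#' The construction-by-design oracle: applies the selection rules to the
#' planted metadata alone (no signal processing). Impacts are generated so
#' their kinematics always satisfy the direction and noise checks, and the
#' label timeline guarantees the matching outcomes, so the only realized
#' randomness that can move a recording between "included" and "excluded"
#' is its IR draw against the fitted threshold: a planted impact with a
#' low-tail IR draw is excluded, and an off-teeth recording with a
#' high-tail draw is (correctly, by the rules) a nonimpact.
#'
#' @param truth Truth table from [generate_cohort()].
#' @param ir_model The fitted `ir_mixture` used by the builder.
#' @return Character vector parallel to `truth`: `"impact"`,
#'   `"nonimpact"`, or `"excluded"`.
#' @export
expected_ground_truth <- function(truth, ir_model) {
  on <- classify_placement(truth$ir_reading, ir_model) == "on_teeth"
  ifelse(!on | truth$class == "no_view", "excluded",
         ifelse(truth$class == "impact", "impact", "nonimpact"))
}
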