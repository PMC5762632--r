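#' Fit the on/off-teeth infrared threshold for one subject-event
#'
#' IR proximity readings over a subject-event are typically bimodal: a low
#' off-teeth mode and a high on-teeth mode. A two-component 1-D Gaussian
#' mixture is fitted by expectation-maximization with deterministic
#' initialization (component means at the 25th/75th percentiles of the
#' readings, equal weights), and the placement threshold is the weighted
#' density crossing between the two component means. When the means are
#' closer than the pooled standard deviation the fit is flagged degenerate
#' and the threshold falls back to the midpoint of the means.
#'
#' @param readings Numeric vector of IR readings for one subject-event
#'   (at least 10).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return Object of class `ir_mixture`: component means/sds/weights
#'   (ordered low, high), `threshold`, `degenerate`, and the fit log
#'   likelihood.
#' @export
fit_ir_threshold <- function(readings, max_iter = 500, tol = 1e-10) {
  x <- as.numeric(readings)
  if (length(x) < 10)
    stop("insufficient data: IR threshold fit needs at least 10 readings",
         call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite IR readings", call. = FALSE)
  mu <- as.numeric(stats::quantile(x, c(0.25, 0.75)))
  sg <- rep(max(stats::sd(x) / 2, 1e-6), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    n1 <- sum(g); n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sg <- sqrt(c(sum(g * (x - mu[1])^2) / n1,
                 sum((1 - g) * (x - mu[2])^2) / n2))
    sg <- pmax(sg, 1e-8 * max(1, diff(range(x))))
    w <- c(n1, n2) / length(x)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (mu[1] > mu[2]) { mu <- rev(mu); sg <- rev(sg); w <- rev(w) }
  pooled_sd <- sqrt(w[1] * sg[1]^2 + w[2] * sg[2]^2)
  mixdens <- function(t) w[1] * stats::dnorm(t, mu[1], sg[1]) +
    w[2] * stats::dnorm(t, mu[2], sg[2])
  f <- function(t) w[1] * stats::dnorm(t, mu[1], sg[1]) -
    w[2] * stats::dnorm(t, mu[2], sg[2])
  lo <- mu[1] + 1e-9 * max(1, abs(mu[1]))
  hi <- mu[2] - 1e-9 * max(1, abs(mu[2]))
  crossing <- if (f(lo) > 0 && f(hi) < 0)
    stats::uniroot(f, c(lo, hi), tol = 1e-12)$root else mean(mu)
  # degenerate when the modes are too close OR the fitted mixture has no
  # meaningful valley between the component means (EM happily carves a
  # narrow low-weight component out of unimodal data, which the separation
  # rule alone cannot catch); a real off/on-teeth split has a crossing
  # density well below both modes
  degenerate <- (mu[2] - mu[1]) < pooled_sd ||
    mixdens(crossing) >= 0.5 * min(mixdens(mu[1]), mixdens(mu[2]))
  threshold <- if (degenerate) mean(mu) else crossing
  structure(list(mean_low = mu[1], sd_low = sg[1], weight_low = w[1],
                 mean_high = mu[2], sd_high = sg[2], weight_high = w[2],
                 threshold = threshold, degenerate = degenerate,
                 loglik = ll_old, n = length(x)),
            class = "ir_mixture")
}

#' @export
print.ir_mixture <- function(x, ...) {
  cat(sprintf("<ir_mixture> n = %d\n", x$n))
  cat(sprintf("  off-teeth: N(%.2f, %.2f) w = %.2f\n",
              x$mean_low, x$sd_low, x$weight_low))
  cat(sprintf("  on-teeth : N(%.2f, %.2f) w = %.2f\n",
              x$mean_high, x$sd_high, x$weight_high))
  cat(sprintf("  threshold %.3f%s\n", x$threshold,
              if (x$degenerate) " (degenerate: midpoint fallback)" else ""))
  invisible(x)
}

#' Classify device placement from an IR reading
#'
#' A reading at or above the fitted threshold is on-teeth (the boundary is
#' inclusive); below is off-teeth.
#'
#' @param rec A [recording()] or a numeric IR reading.
#' @param model An `ir_mixture` from [fit_ir_threshold()].
#' @return `"on_teeth"` or `"off_teeth"` (vectorized over readings).
#' @export
classify_placement <- function(rec, model) {
  ir <- if (inherits(rec, "recording")) rec$ir_reading else as.numeric(rec)
  ifelse(ir >= model$threshold, "on_teeth", "off_teeth")
}

#' @export
predict.ir_mixture <- function(object, newdata, ...) {
  classify_placement(newdata, object)
}

#' Match a recording timestamp against video label intervals
#'
#' The mouthguard clock has 1 s resolution and video synchronization adds
#' at least another second of slack, so a recording is matched to a label
#' interval if the interval dilated by `window` seconds on both sides
#' contains the trigger timestamp. Impact candidacy requires a matched
#' `helmet_contact` interval. Nonimpact candidacy is asymmetric: it
#' requires the timestamp to lie strictly inside an undilated `no_contact`
#' or `idle` interval (dilation exists only to catch clock skew on
#' impacts) while matching no helmet/body/obstructed/no-view interval
#' under dilation.
#'
#' @param rec_ts Trigger timestamp in seconds.
#' @param labels A `video_labels` data frame.
#' @param window Dilation half-width in seconds (default 2).
#' @return List: `matched` (row indices of dilated-matched labels),
#'   `categories`, `impact_candidate`, `nonimpact_candidate`, and
#'   `direction` (the video direction of the first matched helmet contact
#'   by precedence, or `"none"`).
#' @export
match_labels <- function(rec_ts, labels, window = 2) {
  hit <- which(labels$start - window <= rec_ts & rec_ts <= labels$end + window)
  cats <- unique(labels$category[hit])
  helmet <- hit[labels$category[hit] == "helmet_contact"]
  inside_calm <- any(labels$category %in% c("no_contact", "idle") &
                       labels$start < rec_ts & rec_ts < labels$end)
  blockers <- c("helmet_contact", "body_contact", "obstructed", "no_view")
  direction <- if (length(helmet)) labels$direction[helmet[1]] else "none"
  list(matched = hit, categories = cats,
       impact_candidate = length(helmet) > 0,
       nonimpact_candidate = inside_calm && !any(cats %in% blockers),
       direction = direction)
}

DIRECTION_SECTORS <- list(
  frontal = c(-1, 0, 0),  # impact to the front pushes the head posteriorly
  rear    = c(1, 0, 0),
  left    = c(0, -1, 0),  # impact to the player's left pushes the head right
  right   = c(0, 1, 0),
  top     = c(0, 0, -1)
)

#' Check kinematic consistency with the video-observed impact direction
#'
#' The head accelerates away from the impacted surface, so each video
#' direction maps to a 90-degree cone about an anatomical axis (frontal to
#' -AP, rear to +AP, left to -LR, right to +LR, top to -IS under
#' AP/LR/IS = anterior/left/superior). The recording is consistent if
#' either the linear-acceleration vector at the magnitude peak or the
#' end-of-window velocity change lies within the cone (half-angle 45
#' degrees). Video conventions vary between deployments, so the sector map
#' is configurable.
#'
#' @param sig An `anatomical_signals` object.
#' @param direction Video direction: `frontal`, `left`, `right`, `rear`,
#'   or `top`.
#' @param sectors Named list of unit sector-center vectors.
#' @return Logical.
#' @export
direction_consistent <- function(sig, direction,
                                 sectors = DIRECTION_SECTORS) {
  if (!direction %in% names(sectors))
    stop(sprintf("no direction sector defined for '%s'", direction),
         call. = FALSE)
  u <- sectors[[direction]]
  u <- u / sqrt(sum(u^2))
  in_cone <- function(v) {
    nv <- sqrt(sum(v^2))
    nv > 0 && sum(v * u) / nv >= cos(pi / 4)
  }
  peak_acc <- sig$lin_acc[, which.max(sig$lin_acc_mag)]
  dv <- sig$lin_vel[, ncol(sig$lin_vel)]
  in_cone(peak_acc) || in_cone(dv)
}

#' Reject recordings dominated by high-frequency noise
#'
#' With a 1000 Hz sampling rate, content above 200 Hz is undersampled
#' relative to the six-samples-per-period guideline, and recordings with
#' more linear-acceleration periodogram power above 200 Hz than at or below
#' 200 Hz are most likely mouthguard electronics noise rather than helmet
#' contact. Band powers are summed over the three anatomical components
#' (the rectified magnitude series would fold oscillation power into DC and
#' mask the high-frequency content it is meant to catch).
#'
#' @param sig An `anatomical_signals` object.
#' @return `TRUE` to reject (high-frequency power dominates).
#' @export
hf_noise_reject <- function(sig) {
  lo <- 0; hi <- 0
  for (ax in 1:3) {
    p <- periodogram_psd(sig$lin_acc[ax, ])
    f <- attr(p, "freq")
    lo <- lo + sum(p[f <= 200])
    hi <- hi + sum(p[f > 200])
  }
  hi > lo
}

#' Build the labeled ground-truth dataset
#'
#' Applies the conjunctive selection rules to every recording:
#' impacts are on-teeth recordings matched (within the dilated window) to a
#' verified helmet-contact interval whose kinematics are consistent with the
#' video direction and not dominated by high-frequency noise; nonimpacts
#' are on-teeth recordings lying strictly inside no-contact or idle
#' intervals and matching no contact/obstructed/no-view interval. Everything
#' else -- off-teeth recordings, no-view periods, impacts failing the
#' direction or noise checks -- is excluded from both classes. Features are
#' extracted for every included row. The rules are order-independent: the
#' included set does not depend on recording order.
#'
#' @param recs List of [recording()] objects.
#' @param labels A `video_labels` data frame (one event clock with the
#'   recordings).
#' @param calib A [sensor_calibration()].
#' @param ir_model An `ir_mixture` for the recordings' subject-event, or a
#'   named list of `ir_mixture` objects keyed by `subject_event_id`.
#' @param neck A [neck_model_params()].
#' @param window Label dilation half-width in seconds (default 2).
#' @return Data frame of class `labeled_dataset`: `recording_id`, `label`
#'   (`impact`/`nonimpact`), provenance columns (`matched_label`,
#'   `ir_pass`, `direction_pass`, `hf_pass`), and the 411 feature columns.
#'   Zero included rows gives an empty data frame with a warning.
#' @export
build_ground_truth <- function(recs, labels, calib, ir_model,
                               neck = neck_model_params(), window = 2) {
  rows <- list()
  for (rec in recs) {
    model <- if (inherits(ir_model, "ir_mixture")) ir_model else
      ir_model[[rec$subject_event_id]]
    ir_pass <- classify_placement(rec, model) == "on_teeth"
    if (!ir_pass) next
    m <- match_labels(rec$trigger_timestamp, labels, window)
    label <- NA_character_
    direction_pass <- NA
    hf_pass <- NA
    if (m$impact_candidate && m$direction != "none") {
      sig <- preprocess_recording(rec, calib)
      direction_pass <- direction_consistent(sig, m$direction)
      hf_pass <- !hf_noise_reject(sig)
      if (direction_pass && hf_pass) label <- "impact"
    } else if (m$nonimpact_candidate) {
      label <- "nonimpact"
    }
    if (is.na(label)) next
    feats <- extract_feature_vector(rec, calib, neck)
    rows[[length(rows) + 1]] <- c(
      list(recording_id = rec$recording_id, label = label,
           matched_label = if (length(m$matched)) m$matched[1] else NA_integer_,
           ir_pass = ir_pass, direction_pass = direction_pass,
           hf_pass = hf_pass),
      as.list(feats))
  }
  if (!length(rows)) {
    warning("ground-truth selection produced an empty dataset", call. = FALSE)
    return(structure(data.frame(), class = c("labeled_dataset", "data.frame")))
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  rownames(df) <- NULL
  class(df) <- c("labeled_dataset", "data.frame")
  df
}
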