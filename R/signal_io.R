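#' Construct a triggered mouthguard recording
#'
#' A recording is one 10 g-triggered 100 ms window sampled at 1000 Hz
#' (10 ms pre-trigger, 90 ms post-trigger; the trigger sits at sample 11),
#' holding triaxial linear acceleration in g, triaxial angular velocity in
#' rad/s, one infrared (IR) proximity reading, and a trigger timestamp at
#' 1-second resolution.
#'
#' @param recording_id Character scalar, unique within a cohort.
#' @param subject_event_id Character scalar identifying the subject-event
#'   (one player over one game or practice); IR thresholds are fitted per
#'   subject-event.
#' @param trigger_timestamp Trigger time in whole seconds since event start.
#' @param lin_acc_device 3 x 100 numeric matrix, device-frame linear
#'   acceleration in g.
#' @param ang_vel_device 3 x 100 numeric matrix, device-frame angular
#'   velocity in rad/s.
#' @param ir_reading Scalar IR proximity reading, device units.
#' @return Object of class `recording`.
#' @export
recording <- function(recording_id, subject_event_id, trigger_timestamp,
                      lin_acc_device, ang_vel_device, ir_reading) {
  rec <- structure(list(
    recording_id = as.character(recording_id),
    subject_event_id = as.character(subject_event_id),
    trigger_timestamp = as.numeric(trigger_timestamp),
    lin_acc_device = lin_acc_device,
    ang_vel_device = ang_vel_device,
    ir_reading = as.numeric(ir_reading)
  ), class = "recording")
  validate_recording(rec)
  rec
}

N_SAMPLES <- 100L
FS_HZ <- 1000
DT_S <- 1e-3
PRETRIGGER_SAMPLES <- 10L

validate_recording <- function(rec) {
  id <- rec$recording_id
  for (fld in c("lin_acc_device", "ang_vel_device")) {
    m <- rec[[fld]]
    if (!is.matrix(m) || !identical(dim(m), c(3L, N_SAMPLES)))
      stop(sprintf("recording '%s': %s must be a 3x100 matrix (got %s)",
                   id, fld, paste(dim(m), collapse = "x")), call. = FALSE)
    if (!all(is.finite(m)))
      stop(sprintf("recording '%s': non-finite values in %s", id, fld),
           call. = FALSE)
  }
  if (!is.finite(rec$ir_reading))
    stop(sprintf("recording '%s': non-finite ir_reading", id), call. = FALSE)
  if (!is.finite(rec$trigger_timestamp))
    stop(sprintf("recording '%s': non-finite trigger_timestamp", id),
         call. = FALSE)
  invisible(rec)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %s> event %s, trigger t = %g s, IR = %g\n",
              x$recording_id, x$subject_event_id, x$trigger_timestamp,
              x$ir_reading))
  cat(sprintf("  peak |lin acc| %.1f g, peak |ang vel| %.2f rad/s\n",
              max(sqrt(colSums(x$lin_acc_device^2))),
              max(sqrt(colSums(x$ang_vel_device^2)))))
  invisible(x)
}

#' Sensor-to-anatomical calibration
#'
#' Per-subject calibration: the rotation from the device frame to the head
#' anatomical frame (AP = +anterior, LR = +left, IS = +superior,
#' right-handed), the per-sensor low-pass cutoffs, and the lever arm from
#' the sensor origin to the head centre of gravity (used only by the
#' linkage-model features).
#'
#' @param device_to_anatomical 3 x 3 rotation matrix (orthonormal,
#'   determinant +1).
#' @param accel_cutoff Accelerometer bandwidth in Hz (default 500).
#' @param gyro_cutoff Gyroscope bandwidth in Hz (default 184).
#' @param cog_lever_arm Length-3 numeric, metres, sensor origin to head
#'   centre of gravity in the anatomical frame.
#' @return Object of class `sensor_calibration`.
#' @export
sensor_calibration <- function(device_to_anatomical = diag(3),
                               accel_cutoff = 500, gyro_cutoff = 184,
                               cog_lever_arm = c(0, 0, 0)) {
  check_rotation(device_to_anatomical)
  if (accel_cutoff <= 0 || gyro_cutoff <= 0)
    stop("filter cutoffs must be positive", call. = FALSE)
  stopifnot(length(cog_lever_arm) == 3, all(is.finite(cog_lever_arm)))
  structure(list(device_to_anatomical = device_to_anatomical,
                 accel_cutoff = accel_cutoff, gyro_cutoff = gyro_cutoff,
                 cog_lever_arm = as.numeric(cog_lever_arm)),
            class = "sensor_calibration")
}

check_rotation <- function(R, tol = 1e-8) {
  if (!is.matrix(R) || !identical(dim(R), c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > tol || det(R) < 0)
    stop("calibration error: device_to_anatomical is not a proper rotation ",
         "matrix (orthonormal, det = +1)", call. = FALSE)
  invisible(R)
}

VIDEO_CATEGORIES <- c("helmet_contact", "body_contact", "no_contact",
                      "idle", "obstructed", "no_view")
IMPACT_DIRECTIONS <- c("frontal", "left", "right", "rear", "top", "none")

#' Construct a video activity label
#'
#' One labeled time segment from video review: category of player activity
#' and, for helmet contacts, the observed impact direction on the helmet.
#'
#' @param start,end Interval bounds in seconds (event clock), `start <= end`.
#' @param category One of `helmet_contact`, `body_contact`, `no_contact`,
#'   `idle`, `obstructed`, `no_view`.
#' @param direction One of `frontal`, `left`, `right`, `rear`, `top`, or
#'   `none`; non-`none` only for `helmet_contact`.
#' @return One-row data frame with class `video_labels`.
#' @export
video_label <- function(start, end, category, direction = "none") {
  video_labels(data.frame(start = start, end = end, category = category,
                          direction = direction,
                          stringsAsFactors = FALSE))
}

video_labels <- function(df) {
  need <- c("start", "end", "category", "direction")
  if (!all(need %in% names(df)))
    stop("video labels need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$category), VIDEO_CATEGORIES)
  if (length(bad))
    stop(sprintf("unknown video label category '%s'; allowed: %s",
                 bad[1], paste(VIDEO_CATEGORIES, collapse = ", ")),
         call. = FALSE)
  bad_dir <- setdiff(unique(df$direction), IMPACT_DIRECTIONS)
  if (length(bad_dir))
    stop(sprintf("unknown impact direction '%s'; allowed: %s",
                 bad_dir[1], paste(IMPACT_DIRECTIONS, collapse = ", ")),
         call. = FALSE)
  if (any(df$start > df$end))
    stop("video label with start > end", call. = FALSE)
  if (any(df$direction != "none" & df$category != "helmet_contact"))
    stop("direction may be set only for helmet_contact labels", call. = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("video_labels", "data.frame")
  df
}

#' Read video activity labels from CSV
#'
#' Expects columns `start_s`, `end_s`, `category`, `direction`. Intervals
#' are returned sorted by start; overlapping intervals (multiple camera
#' judgments) are preserved as-is.
#'
#' @param path Path to the label CSV.
#' @return A `video_labels` data frame.
#' @export
read_video_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "category", "direction")
  if (!all(need %in% names(df)))
    stop("video label CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  video_labels(data.frame(start = as.numeric(df$start_s),
                          end = as.numeric(df$end_s),
                          category = df$category, direction = df$direction,
                          stringsAsFactors = FALSE))
}

#' Write video activity labels to CSV
#' @param labels A `video_labels` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_video_labels <- function(labels, path) {
  utils::write.csv(data.frame(start_s = labels$start, end_s = labels$end,
                              category = labels$category,
                              direction = labels$direction),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read triggered recordings from a long-format CSV
#'
#' The CSV dialect is long: one row per sample with columns `recording_id`,
#' `subject_event_id`, `trigger_ts`, `t_ms` (0..99; the trigger sits at
#' `t_ms = 10`), `ax_g`, `ay_g`, `az_g`, `wx_rps`, `wy_rps`, `wz_rps`, `ir`.
#' Every recording must contribute exactly 100 monotone samples.
#'
#' @param path Path to the recordings CSV.
#' @param dialect File dialect; only `"csv"` is supported.
#' @return List of [recording()] objects ordered by trigger timestamp then
#'   recording id.
#' @export
read_recordings <- function(path, dialect = "csv") {
  if (!identical(dialect, "csv"))
    stop(sprintf("unsupported recordings dialect '%s'; only 'csv' is available",
                 dialect), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "subject_event_id", "trigger_ts", "t_ms",
            "ax_g", "ay_g", "az_g", "wx_rps", "wy_rps", "wz_rps", "ir")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("recordings CSV missing channel column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) return(list())
  recs <- lapply(split(df, df$recording_id), function(d) {
    id <- d$recording_id[1]
    if (nrow(d) != N_SAMPLES)
      stop(sprintf("schema error: recording '%s' has %d samples, expected 100",
                   id, nrow(d)), call. = FALSE)
    d <- d[order(d$t_ms), , drop = FALSE]
    if (!identical(as.integer(d$t_ms), 0:99))
      stop(sprintf("schema error: recording '%s' has non-monotone or gapped t_ms",
                   id), call. = FALSE)
    recording(id, d$subject_event_id[1], d$trigger_ts[1],
              rbind(d$ax_g, d$ay_g, d$az_g),
              rbind(d$wx_rps, d$wy_rps, d$wz_rps),
              d$ir[1])
  })
  ord <- order(vapply(recs, `[[`, 0, "trigger_timestamp"),
               vapply(recs, `[[`, "", "recording_id"))
  unname(recs[ord])
}

#' Write triggered recordings to a long-format CSV
#' @param recs List of [recording()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recordings <- function(recs, path) {
  header <- "recording_id,subject_event_id,trigger_ts,t_ms,ax_g,ay_g,az_g,wx_rps,wy_rps,wz_rps,ir"
  rows <- lapply(recs, function(r) {
    validate_recording(r)
    data.frame(recording_id = r$recording_id,
               subject_event_id = r$subject_event_id,
               trigger_ts = r$trigger_timestamp,
               t_ms = 0:99,
               ax_g = r$lin_acc_device[1, ], ay_g = r$lin_acc_device[2, ],
               az_g = r$lin_acc_device[3, ],
               wx_rps = r$ang_vel_device[1, ], wy_rps = r$ang_vel_device[2, ],
               wz_rps = r$ang_vel_device[3, ],
               ir = r$ir_reading)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) {
    writeLines(header, path)
  } else {
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a feature table with its registry version header
#'
#' The on-disk format is CSV preceded by a comment header line
#' `# impactkit_feature_registry <version> <hash>`. Reading verifies the
#' version and the registry hash; a mismatch is an explicit error rather
#' than a silent coercion.
#'
#' @param table Data frame with one row per recording: metadata columns
#'   (`recording_id`, optionally `label` and provenance flags) plus the 411
#'   registry feature columns in canonical order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  reg <- feature_registry()
  if (anyDuplicated(names(table)))
    stop("feature table has duplicate column names", call. = FALSE)
  feat <- intersect(names(table), reg)
  if (!identical(feat, as.character(reg)))
    stop(sprintf("versioned-registry error: table carries %d registry columns, expected all 411 in canonical order",
                 length(feat)), call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# impactkit_feature_registry %s %s",
                     REGISTRY_VERSION, registry_hash(reg)), con)
  # 17 significant digits round-trip IEEE doubles exactly
  out <- table
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path Path to the feature table CSV.
#' @return Data frame with metadata and 411 feature columns.
#' @export
read_feature_table <- function(path) {
  first <- readLines(path, n = 1)
  parts <- strsplit(first, " ")[[1]]
  if (length(parts) != 4 || parts[1] != "#" ||
      parts[2] != "impactkit_feature_registry")
    stop("not a feature table: missing registry header", call. = FALSE)
  if (parts[3] != REGISTRY_VERSION || parts[4] != registry_hash())
    stop(sprintf("versioned-registry error: file registry %s/%s does not match installed registry %s/%s",
                 parts[3], parts[4], REGISTRY_VERSION, registry_hash()),
         call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, skip = 1)
  reg <- feature_registry()
  if (!identical(intersect(names(df), reg), as.character(reg)))
    stop("versioned-registry error: feature columns do not match the registry",
         call. = FALSE)
  df
}

#' Serialize a trained classifier to JSON
#'
#' Stores everything needed to reproduce the decision function: selected
#' feature names in selection order, standardization statistics, kernel
#' parameter, support vectors, dual coefficients, bias, sign orientation,
#' and the registry version.
#'
#' @param model An `impact_classifier` from [train_impact_classifier()] or
#'   [train_rbf_svm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "impact_classifier"))
  payload <- list(
    registry_version = REGISTRY_VERSION,
    registry_hash = registry_hash(),
    features = model$features,
    center = model$center, scale = model$scale,
    gamma = model$gamma, cost = model$cost,
    support_vectors = model$support_vectors,
    dual_coefs = model$dual_coefs, rho = model$rho, sign = model$sign,
    decision_threshold = model$decision_threshold
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a trained classifier serialized by [write_classifier()]
#' @param path Path to the classifier JSON.
#' @return An `impact_classifier` object.
#' @export
read_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$registry_hash, registry_hash()))
    stop("classifier was serialized against a different feature registry",
         call. = FALSE)
  sv <- p$support_vectors
  if (is.null(dim(sv))) sv <- matrix(sv, ncol = length(p$features))
  structure(list(
    features = p$features,
    center = stats::setNames(as.numeric(p$center), p$features),
    scale = stats::setNames(as.numeric(p$scale), p$features),
    gamma = p$gamma, cost = p$cost,
    support_vectors = sv,
    dual_coefs = as.numeric(p$dual_coefs), rho = p$rho, sign = p$sign,
    decision_threshold = p$decision_threshold
  ), class = "impact_classifier")
}
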