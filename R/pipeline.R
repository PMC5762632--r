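#' Extract the feature table for a set of recordings
#'
#' One 411-feature row per readable recording, in input order. A recording
#' that fails extraction is skipped with a message and reported in the
#' `skipped` attribute; rows are never silently dropped.
#'
#' @param recs List of [recording()] objects.
#' @param calib A [sensor_calibration()].
#' @param neck A [neck_model_params()].
#' @return Data frame: `recording_id`, `trigger_ts`, `ir_reading`, plus the
#'   411 registry feature columns; attribute `skipped` lists failed ids.
#' @export
extract_features <- function(recs, calib, neck = neck_model_params()) {
  rows <- list()
  skipped <- character(0)
  for (rec in recs) {
    feats <- tryCatch(extract_feature_vector(rec, calib, neck),
                      error = function(e) {
                        message(sprintf("skipping recording '%s': %s",
                                        rec$recording_id, conditionMessage(e)))
                        NULL
                      })
    if (is.null(feats)) {
      skipped <- c(skipped, rec$recording_id)
      next
    }
    rows[[length(rows) + 1]] <- c(
      list(recording_id = rec$recording_id,
           trigger_ts = rec$trigger_timestamp,
           ir_reading = rec$ir_reading),
      as.list(feats))
  }
  df <- if (length(rows)) do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  else data.frame()
  rownames(df) <- NULL
  structure(df, skipped = skipped)
}

#' Train and cross-validate the impact classifier on a labeled dataset
#'
#' The central model fit: optionally run sequential forward feature
#' selection under the configured leave-one-out cost, fit the final
#' RBF-SVM on all rows with the selected features, and report leave-one-out
#' cross-validated confusion counts, performance metrics, ROC/PR curves,
#' and the peak-acceleration thresholding baseline on the same rows.
#' Supplying `features` bypasses selection (for instance to refit a
#' published feature list).
#'
#' @param dataset A `labeled_dataset` from [build_ground_truth()], or any
#'   data frame with a `label` column and registry feature columns.
#' @param cfg A [classifier_config()].
#' @param features Optional character vector of feature names to use
#'   as-is, skipping selection.
#' @param verbose Print selection progress.
#' @return Object of class `impact_classifier` extending [train_rbf_svm()]
#'   with `selection` (trace), `loocv` (decision values, confusion counts,
#'   metrics, `roc_pr`), `baseline` (`roc_pr` of peak-acceleration
#'   thresholding), and `n`.
#' @export
train_impact_classifier <- function(dataset, cfg = classifier_config(),
                                    features = NULL, verbose = FALSE) {
  y <- as.character(dataset$label)
  if (length(unique(y)) < 2)
    stop("training error: dataset must contain impacts and nonimpacts",
         call. = FALSE)
  reg <- feature_registry()
  X <- as.matrix(dataset[, intersect(names(dataset), reg), drop = FALSE])
  selection <- NULL
  if (is.null(features)) {
    sel <- sequential_forward_selection(X, y, cfg, verbose = verbose)
    features <- sel$features
    selection <- sel$trace
  } else {
    stopifnot(all(features %in% colnames(X)))
  }
  Xs <- X[, features, drop = FALSE]
  model <- train_rbf_svm(Xs, y, cfg)
  dv <- loocv_decision_values(Xs, y, cfg)
  pred <- ifelse(dv >= 0, "impact", "nonimpact")
  TP <- sum(pred == "impact" & y == "impact")
  TN <- sum(pred == "nonimpact" & y == "nonimpact")
  FP <- sum(pred == "impact" & y == "nonimpact")
  FN <- sum(pred == "nonimpact" & y == "impact")
  metrics <- confusion_metrics(TP, TN, FP, FN)
  curves <- roc_pr_curves(as.numeric(dv), y)
  baseline <- baseline_threshold_curves(dataset[["la_peak_mag"]], y)
  model$selection <- selection
  model$loocv <- list(decision_values = as.numeric(dv), labels = y,
                      counts = c(TP = TP, TN = TN, FP = FP, FN = FN),
                      metrics = metrics, curves = curves)
  model$baseline <- baseline
  model$n <- length(y)
  model
}

#' @export
print.impact_classifier <- function(x, ...) {
  cat(sprintf("<impact_classifier> RBF-SVM, %d feature(s), C = %g, gamma = %g\n",
              length(x$features), x$cost, x$gamma))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  if (!is.null(x$loocv)) {
    m <- format_metrics_percent(x$loocv$metrics)
    cat(sprintf("  LOOCV (n = %d): sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%, precision %.1f%%\n",
                x$n, m["sensitivity"], m["specificity"], m["accuracy"],
                m["precision"]))
    cat(sprintf("  AUC-ROC %.3f, AUC-PR %.3f\n",
                x$loocv$curves$auc_roc, x$loocv$curves$auc_pr))
  }
  invisible(x)
}

#' @export
summary.impact_classifier <- function(object, ...) {
  print(object)
  if (!is.null(object$selection)) {
    cat("  selection trace:\n")
    print(object$selection, row.names = FALSE)
  }
  if (!is.null(object$baseline))
    cat(sprintf("  peak-acceleration baseline AUC-ROC %.3f\n",
                object$baseline$auc_roc))
  invisible(object)
}

#' @export
plot.impact_classifier <- function(x, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (is.null(x$loocv)) stop("no cross-validation results to plot",
                             call. = FALSE)
  if (which == "roc") {
    graphics::plot(x$loocv$curves$roc$fpr, x$loocv$curves$roc$tpr,
                   type = "l", xlab = "1 - specificity",
                   ylab = "sensitivity", main = "LOOCV ROC", ...)
    if (!is.null(x$baseline))
      graphics::lines(x$baseline$roc$fpr, x$baseline$roc$tpr, lty = 2)
    graphics::abline(0, 1, col = "grey")
  } else {
    graphics::plot(x$loocv$curves$pr$recall, x$loocv$curves$pr$precision,
                   type = "l", xlab = "recall", ylab = "precision",
                   main = "LOOCV precision-recall", ylim = c(0, 1), ...)
    if (!is.null(x$baseline))
      graphics::lines(x$baseline$pr$recall, x$baseline$pr$precision, lty = 2)
  }
  invisible(x)
}

#' Classify every recording of an event
#'
#' The deployment-style two-stage flow: recordings below the IR placement
#' threshold are rejected first (`ir_rejected`), and only on-teeth
#' recordings are classified by the trained SVM into `impact` or
#' `nonimpact`. A recording that fails feature extraction gets disposition
#' `error`. Dispositions partition the input.
#'
#' @param recs List of [recording()] objects.
#' @param ir_model An `ir_mixture` (or named list keyed by
#'   subject-event id).
#' @param model A trained `impact_classifier`.
#' @param calib A [sensor_calibration()].
#' @param neck A [neck_model_params()].
#' @return Data frame of class `event_classification`: `recording_id`,
#'   `trigger_ts`, `disposition`, `decision_value`; attribute `counts`
#'   (named disposition counts).
#' @export
classify_recordings <- function(recs, ir_model, model, calib,
                                neck = neck_model_params()) {
  out <- lapply(recs, function(rec) {
    m <- if (inherits(ir_model, "ir_mixture")) ir_model else
      ir_model[[rec$subject_event_id]]
    if (classify_placement(rec, m) == "off_teeth")
      return(data.frame(recording_id = rec$recording_id,
                        trigger_ts = rec$trigger_timestamp,
                        disposition = "ir_rejected",
                        decision_value = NA_real_))
    feats <- tryCatch(extract_feature_vector(rec, calib, neck),
                      error = function(e) NULL)
    if (is.null(feats))
      return(data.frame(recording_id = rec$recording_id,
                        trigger_ts = rec$trigger_timestamp,
                        disposition = "error", decision_value = NA_real_))
    dv <- decision_values(model, as.data.frame(as.list(feats),
                                               check.names = FALSE))
    data.frame(recording_id = rec$recording_id,
               trigger_ts = rec$trigger_timestamp,
               disposition = ifelse(dv >= model$decision_threshold,
                                    "impact", "nonimpact"),
               decision_value = dv)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  counts <- table(factor(df$disposition,
                         levels = c("impact", "nonimpact", "ir_rejected",
                                    "error")))
  structure(df, counts = c(counts), class = c("event_classification",
                                              "data.frame"))
}
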