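#' Classifier configuration
#'
#' @param cost_function Selection cost: `"auc"` (1 - area under the ROC
#'   curve) or `"f_measure"` (1 - F-measure at the zero decision
#'   threshold), both computed from leave-one-out cross-validation so that
#'   selection optimizes generalization rather than training fit.
#' @param C Soft-margin regularization of the SVM (> 0, default 1).
#' @param gamma RBF kernel width; `NULL` (default) uses 1/d on the
#'   standardized features.
#' @param standardize Standardize features with training-set statistics
#'   (default `TRUE`).
#' @param max_features Forward-selection cap (default 10).
#' @param seed Integer seed recorded with the model.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(cost_function = c("auc", "f_measure"),
                              C = 1, gamma = NULL, standardize = TRUE,
                              max_features = 10, seed = 1L) {
  cost_function <- match.arg(cost_function)
  if (C <= 0) stop("C must be positive", call. = FALSE)
  if (!is.null(gamma) && gamma <= 0) stop("gamma must be positive",
                                          call. = FALSE)
  structure(list(cost_function = cost_function, C = C, gamma = gamma,
                 standardize = standardize, max_features = max_features,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity TP/(TP+FN), precision TP/(TP+FP), specificity TN/(TN+FP),
#' accuracy (TP+TN)/n, and the F-measure (harmonic mean of sensitivity and
#' precision). A zero denominator yields 0 for that metric and sets the
#' `degenerate` attribute.
#'
#' @param TP,TN,FP,FN Nonnegative confusion counts.
#' @return Named numeric vector (proportions in `[0, 1]`) with components
#'   `sensitivity`, `specificity`, `accuracy`, `precision`, `f_measure`.
#' @seealso [format_metrics_percent()] for Table-style one-decimal
#'   percentage display.
#' @export
confusion_metrics <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  n <- TP + TN + FP + FN
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  sens <- safe_div(TP, TP + FN)
  prec <- safe_div(TP, TP + FP)
  spec <- safe_div(TN, TN + FP)
  acc <- safe_div(TP + TN, n)
  f <- safe_div(2 * sens * prec, sens + prec)
  structure(c(sensitivity = sens, specificity = spec, accuracy = acc,
              precision = prec, f_measure = f),
            counts = c(TP = TP, TN = TN, FP = FP, FN = FN),
            degenerate = degenerate)
}

#' Round half away from zero
#' @param x Numeric.
#' @param digits Decimal digits.
#' @return Rounded numeric (display convention for reported percentages).
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format metrics as one-decimal percentages
#' @param metrics Output of [confusion_metrics()].
#' @return Named numeric vector of percentages rounded to one decimal,
#'   half away from zero.
#' @export
format_metrics_percent <- function(metrics) {
  round_half_away(100 * as.numeric(metrics), 1) |>
    stats::setNames(names(metrics))
}

standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$center), 2, st$scale, "/")
}

#' Train an RBF-kernel support vector machine
#'
#' Fits a two-class soft-margin SVM with a radial-basis-function kernel on
#' the given feature columns. Features are standardized with training-set
#' statistics (stored in the model); the decision value is oriented so that
#' values at or above zero classify as impact. The fitted decision function
#' is fully determined by the stored support vectors, dual coefficients,
#' kernel width, and bias, and [decision_values()] reproduces it from the
#' serialized form.
#'
#' @param X Numeric matrix or data frame, rows = samples.
#' @param y Labels: `"impact"` / `"nonimpact"`.
#' @param cfg A [classifier_config()].
#' @return Object of class `impact_classifier`.
#' @export
train_rbf_svm <- function(X, y, cfg = classifier_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.character(y)
  if (length(unique(y)) < 2)
    stop("training error: both classes must be present", call. = FALSE)
  if (!all(y %in% c("impact", "nonimpact")))
    stop("labels must be 'impact' or 'nonimpact'", call. = FALSE)
  st <- if (cfg$standardize) standardize_fit(X) else
    list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  Z <- standardize_apply(X, st)
  gamma <- if (is.null(cfg$gamma)) 1 / ncol(Z) else cfg$gamma
  fit <- e1071::svm(Z, factor(y, levels = c("impact", "nonimpact")),
                    kernel = "radial", gamma = gamma, cost = cfg$C,
                    scale = FALSE)
  dv <- attr(stats::predict(fit, Z, decision.values = TRUE),
             "decision.values")[, 1]
  # orient so impacts score high regardless of libsvm's internal label order
  sgn <- if (mean(dv[y == "impact"]) >= mean(dv[y == "nonimpact"])) 1 else -1
  structure(list(
    features = colnames(X),
    center = st$center, scale = st$scale,
    gamma = gamma, cost = cfg$C,
    support_vectors = unname(as.matrix(fit$SV)),
    dual_coefs = as.numeric(fit$coefs), rho = fit$rho, sign = sgn,
    decision_threshold = 0,
    config = cfg
  ), class = "impact_classifier")
}

#' Decision values of a trained classifier
#'
#' Evaluates the kernel expansion
#' `sign * (sum_i alpha_i exp(-gamma ||z - sv_i||^2) - rho)` on
#' standardized inputs; positive values indicate impact.
#'
#' @param model An `impact_classifier`.
#' @param X Matrix or data frame containing the model's feature columns.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, X) {
  Xdf <- as.data.frame(X)
  X <- if (all(model$features %in% names(Xdf))) {
    as.matrix(Xdf[, model$features, drop = FALSE])
  } else if (ncol(Xdf) == length(model$features)) {
    as.matrix(Xdf)     # positional match for unnamed inputs
  } else {
    stop("newdata does not contain the model's feature columns",
         call. = FALSE)
  }
  Z <- standardize_apply(X, list(center = model$center, scale = model$scale))
  SV <- model$support_vectors
  d2 <- outer(rowSums(Z^2), rowSums(SV^2), "+") - 2 * Z %*% t(SV)
  K <- exp(-model$gamma * pmax(d2, 0))
  model$sign * (as.numeric(K %*% model$dual_coefs) - model$rho)
}

#' @export
predict.impact_classifier <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  dv <- decision_values(object, newdata)
  if (type == "decision") return(dv)
  ifelse(dv >= object$decision_threshold, "impact", "nonimpact")
}

#' Leave-one-out cross-validated decision values
#'
#' For each sample, the classifier (including the standardization
#' statistics) is fitted on the remaining n - 1 samples and evaluated on
#' the held-out sample, so no fold's value ever uses its own sample. A fold
#' whose training set collapses to one class yields a prior-free decision
#' value 0 and is flagged, so n is conserved.
#'
#' @param X Feature matrix (rows = samples).
#' @param y Labels (`impact`/`nonimpact`).
#' @param cfg A [classifier_config()].
#' @return Numeric vector of n held-out decision values, with attribute
#'   `flagged` marking degenerate folds.
#' @export
loocv_decision_values <- function(X, y, cfg = classifier_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out needs at least 3 samples", call. = FALSE)
  y <- as.character(y)
  dv <- numeric(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      flagged[i] <- TRUE
      dv[i] <- 0
      next
    }
    dv[i] <- fold_decision_value(X[-i, , drop = FALSE], ytr,
                                 X[i, , drop = FALSE], cfg)
  }
  structure(dv, flagged = flagged)
}

# One LOOCV fold on the fast path: standardize with training-fold statistics,
# fit libsvm without fitted values, and evaluate the kernel expansion
# directly for the held-out sample. Orientation (which decision sign means
# impact) is established from the training rows themselves, so the held-out
# sample never influences it.
fold_decision_value <- function(Xtr, ytr, xte, cfg) {
  if (cfg$standardize) {
    st <- standardize_fit(Xtr)
    Ztr <- standardize_apply(Xtr, st)
    zte <- standardize_apply(xte, st)
  } else {
    Ztr <- Xtr
    zte <- xte
  }
  gamma <- if (is.null(cfg$gamma)) 1 / ncol(Ztr) else cfg$gamma
  fit <- e1071::svm(Ztr, factor(ytr, levels = c("impact", "nonimpact")),
                    kernel = "radial", gamma = gamma, cost = cfg$C,
                    scale = FALSE, fitted = FALSE)
  SV <- as.matrix(fit$SV)
  kexp <- function(Z) {
    d2 <- outer(rowSums(Z^2), rowSums(SV^2), "+") - 2 * Z %*% t(SV)
    as.numeric(exp(-gamma * pmax(d2, 0)) %*% fit$coefs) - fit$rho
  }
  dtr <- kexp(Ztr)
  sgn <- if (mean(dtr[ytr == "impact"]) >= mean(dtr[ytr == "nonimpact"]))
    1 else -1
  sgn * kexp(zte)
}

#' ROC and precision-recall curves with trapezoidal areas
#'
#' Sweeps the classification threshold over the unique scores (ties
#' grouped), predicting impact where the score is at or above the
#' threshold. The ROC curve is (false positive rate, sensitivity) closed at
#' (0,0) and (1,1); the PR curve is (recall, precision) over the same sweep
#' with the recall = 0 endpoint extended at the first precision value.
#' Areas by the trapezoid rule.
#'
#' @param scores Numeric scores, higher = more impact-like.
#' @param y Labels (`impact`/`nonimpact`).
#' @return List of class `roc_pr`: data frames `roc` (fpr, tpr,
#'   threshold) and `pr` (recall, precision, threshold), plus `auc_roc`
#'   and `auc_pr`.
#' @export
roc_pr_curves <- function(scores, y) {
  y <- as.character(y)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  pos <- y == "impact"
  if (!any(pos) || all(pos))
    stop("undefined curve: both classes must be present", call. = FALSE)
  np <- sum(pos); nn <- sum(!pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(pos & scores >= t), 0)
  fp <- vapply(thr, function(t) sum(!pos & scores >= t), 0)
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  if (tpr[length(tpr)] != 1 || fpr[length(fpr)] != 1) {
    tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  }
  auc_roc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  rec <- tp / np
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  rec_full <- c(0, rec)
  prec_full <- c(prec[1], prec)
  o <- order(rec_full, -prec_full)
  rec_full <- rec_full[o]; prec_full <- prec_full[o]
  auc_pr <- sum(diff(rec_full) *
                  (utils::head(prec_full, -1) + utils::tail(prec_full, -1)) / 2)
  structure(list(
    roc = data.frame(fpr = fpr, tpr = tpr,
                     threshold = c(Inf, thr, -Inf)[seq_along(fpr)]),
    pr = data.frame(recall = rec_full, precision = prec_full),
    auc_roc = auc_roc, auc_pr = auc_pr
  ), class = "roc_pr")
}

#' Peak-acceleration thresholding baseline
#'
#' The conventional detector: classify by thresholding the peak linear
#' acceleration vector magnitude alone, sweeping the threshold across the
#' observed range. Identical sweep semantics to [roc_pr_curves()] with the
#' peak magnitude as the score.
#'
#' @param peak_acc_magnitude Per-sample peak |linear acceleration| in g.
#' @param y Labels.
#' @return A `roc_pr` object.
#' @export
baseline_threshold_curves <- function(peak_acc_magnitude, y) {
  roc_pr_curves(peak_acc_magnitude, y)
}

loocv_cost <- function(X, y, cfg) {
  dv <- loocv_decision_values(X, y, cfg)
  if (cfg$cost_function == "auc") {
    1 - roc_pr_curves(as.numeric(dv), y)$auc_roc
  } else {
    pred <- dv >= 0
    pos <- y == "impact"
    m <- confusion_metrics(sum(pred & pos), sum(!pred & !pos),
                           sum(pred & !pos), sum(!pred & pos))
    1 - m[["f_measure"]]
  }
}

#' Sequential forward feature selection
#'
#' Greedy wrapper selection: at each step every unselected registry feature
#' is scored by the leave-one-out cross-validated cost (1 - AUC or
#' 1 - F-measure) of the candidate feature set, the best strictly improving
#' candidate is accepted, and selection stops when no candidate strictly
#' improves the cost or `max_features` is reached. Cost ties break toward
#' the lowest registry index, making the procedure deterministic.
#'
#' @param X Feature matrix with registry-ordered columns.
#' @param y Labels.
#' @param cfg A [classifier_config()].
#' @param verbose Print per-step progress.
#' @return List: `features` (selected names, in selection order), `trace`
#'   (data frame of accepted steps with costs, non-increasing).
#' @export
sequential_forward_selection <- function(X, y, cfg = classifier_config(),
                                         verbose = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  selected <- integer(0)
  best_cost <- Inf
  trace <- list()
  repeat {
    if (length(selected) >= cfg$max_features) break
    candidates <- setdiff(seq_len(ncol(X)), selected)
    costs <- vapply(candidates, function(j)
      loocv_cost(X[, c(selected, j), drop = FALSE], y, cfg), 0)
    j_best <- candidates[which.min(costs)]  # which.min takes the first: lowest registry index on ties
    c_best <- min(costs)
    if (!(c_best < best_cost)) break
    selected <- c(selected, j_best)
    best_cost <- c_best
    trace[[length(trace) + 1]] <- data.frame(
      step = length(selected), feature = colnames(X)[j_best], cost = c_best)
    if (verbose)
      message(sprintf("step %d: + %s (cost %.4f)", length(selected),
                      colnames(X)[j_best], c_best))
  }
  list(features = colnames(X)[selected],
       trace = do.call(rbind, trace))
}
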