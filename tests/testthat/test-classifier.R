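# exhaustive threshold-enumeration oracle for ROC/PR areas
roc_pr_oracle <- function(scores, y) {
  pos <- y == "impact"
  thr <- c(sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- t(vapply(thr, function(t) {
    tp <- sum(pos & scores >= t); fp <- sum(!pos & scores >= t)
    c(fpr = fp / sum(!pos), tpr = tp / sum(pos),
      rec = tp / sum(pos), prec = if (tp + fp > 0) tp / (tp + fp) else 1)
  }, numeric(4)))
  fpr <- c(0, pts[, "fpr"]); tpr <- c(0, pts[, "tpr"])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  rec <- c(0, pts[, "rec"]); prec <- c(pts[1, "prec"], pts[, "prec"])
  aupr <- sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
  c(auc = auc, aupr = aupr)
}

test_that("confusion metrics evaluate the defining formulas", {
  m <- confusion_metrics(15, 15, 1, 1)
  expect_equal(as.numeric(format_metrics_percent(m)[1:4]),
               rep(93.8, 4))  # all four rates are 15/16 or (15+15)/32
  # direct formula evaluation: F of sensitivity .904 and precision .946
  expect_equal(2 * 0.904 * 0.946 / (0.904 + 0.946), 0.9245,
               tolerance = 1e-4)
  m <- confusion_metrics(141, 223, 8, 15)
  expect_equal(unname(m["f_measure"]),
               2 * (141 / 156) * (141 / 149) / (141 / 156 + 141 / 149))

  z <- confusion_metrics(0, 0, 0, 5)
  expect_equal(unname(z["precision"]), 0)
  expect_true(attr(z, "degenerate"))

  # display rounding is half away from zero at one decimal
  expect_equal(round_half_away(68.75, 1), 68.8)
  expect_equal(round_half_away(-0.05, 1), -0.1)
})

test_that("RBF-SVM training separates, is deterministic, and matches the kernel expansion", {
  X <- matrix(c(rep(-1, 10), rep(1, 10)) + rnorm(20, sd = 0.01), ncol = 1)
  y <- rep(c("nonimpact", "impact"), each = 10)
  set.seed(121)
  fit <- train_rbf_svm(X, y)
  expect_equal(unname(predict(fit, X)), y)

  fit2 <- train_rbf_svm(X, y)
  expect_equal(decision_values(fit, X), decision_values(fit2, X))

  # brute-force kernel-sum evaluation on 10 points
  set.seed(122)
  Xr <- matrix(rnorm(40), ncol = 2, dimnames = list(NULL, c("a", "b")))
  yr <- rep(c("impact", "nonimpact"), 10)
  fr <- train_rbf_svm(Xr, yr)
  Z <- scale(Xr, center = fr$center, scale = fr$scale)
  dv_brute <- vapply(1:10, function(i) {
    k <- vapply(seq_len(nrow(fr$support_vectors)), function(s)
      exp(-fr$gamma * sum((Z[i, ] - fr$support_vectors[s, ])^2)), 0)
    fr$sign * (sum(k * fr$dual_coefs) - fr$rho)
  }, 0)
  expect_equal(decision_values(fr, Xr[1:10, ]), dv_brute, tolerance = 1e-8)

  expect_error(train_rbf_svm(X, rep("impact", 20)), "training error")
})

test_that("serialized classifiers reproduce their decision function", {
  set.seed(123)
  X <- matrix(rnorm(60), ncol = 3)
  colnames(X) <- feature_registry()[1:3]
  y <- rep(c("impact", "nonimpact"), 10)
  fit <- train_rbf_svm(X, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(fit, path)
  back <- read_classifier(path)
  expect_equal(decision_values(back, X), decision_values(fit, X),
               tolerance = 1e-12)
})

test_that("LOOCV values never use the held-out sample and are order-invariant", {
  set.seed(131)
  n <- 24
  X <- matrix(rnorm(n * 2), ncol = 2)
  X[, 1] <- X[, 1] + rep(c(3, 0), each = n / 2)
  y <- rep(c("impact", "nonimpact"), each = n / 2)
  dv <- loocv_decision_values(X, y)

  # hand refit per fold through the public single-model route
  for (i in c(1, 13)) {
    fit <- train_rbf_svm(X[-i, ], y[-i])
    expect_equal(as.numeric(dv[i]),
                 decision_values(fit, X[i, , drop = FALSE]) *
                   sign(1), tolerance = 1e-10)
  }

  # permuting sample order leaves per-sample values unchanged up to the
  # SMO solver's working tolerance
  set.seed(132)
  perm <- sample(n)
  dv_perm <- loocv_decision_values(X[perm, ], y[perm])
  expect_equal(as.numeric(dv_perm), as.numeric(dv)[perm], tolerance = 1e-3)

  # constant feature: values independent of the left-out index, all folds equal
  Xc <- matrix(1, n, 1)
  dvc <- suppressWarnings(loocv_decision_values(Xc, y))
  expect_lt(diff(range(dvc[y == "impact"])), 1e-8)

  # 3 separable points: signs recoverable by hand
  X3 <- matrix(c(-2, 2, 2.2), ncol = 1)
  y3 <- c("nonimpact", "impact", "impact")
  dv3 <- loocv_decision_values(X3, y3)
  expect_true(dv3[2] > 0 && dv3[3] > 0)

  # leaving out the only member of a class gives a flagged single-class
  # fold scored 0; the other folds still train on both classes
  y_deg <- c("nonimpact", "impact", "impact")
  dvd <- loocv_decision_values(matrix(c(0, 1, 2)), y_deg)
  expect_true(attr(dvd, "flagged")[1])
  expect_equal(as.numeric(dvd[1]), 0)
  expect_false(any(attr(dvd, "flagged")[2:3]))
})

test_that("ROC and PR sweeps match exhaustive enumeration and pROC", {
  y <- rep(c("impact", "nonimpact"), each = 5)
  perfect <- c(6:10, 1:5)
  r <- roc_pr_curves(perfect, y)
  expect_equal(r$auc_roc, 1)
  expect_equal(r$auc_pr, 1)
  expect_equal(roc_pr_curves(-perfect, y)$auc_roc, 0)

  set.seed(141)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    scores <- rnorm(n)
    yy <- sample(rep(c("impact", "nonimpact"), length.out = n))
    if (length(unique(yy)) < 2) next
    r <- roc_pr_curves(scores, yy)
    o <- roc_pr_oracle(scores, yy)
    expect_equal(r$auc_roc, unname(o["auc"]), tolerance = 1e-12)
    expect_equal(r$auc_pr, unname(o["aupr"]), tolerance = 1e-12)
  }

  skip_if_not_installed("pROC")
  set.seed(142)
  scores <- rnorm(40); yy <- sample(rep(c("impact", "nonimpact"), 20))
  r <- roc_pr_curves(scores, yy)
  ref <- as.numeric(pROC::auc(pROC::roc(response = yy, predictor = scores,
                                        levels = c("nonimpact", "impact"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(r$auc_roc, ref, tolerance = 1e-12)

  expect_error(roc_pr_curves(1:5, rep("impact", 5)), "undefined curve")
})

test_that("ties in scores collapse to a single threshold", {
  scores <- c(3, 3, 3, 1, 1)
  y <- c("impact", "impact", "nonimpact", "nonimpact", "nonimpact")
  r <- roc_pr_curves(scores, y)
  # one intermediate operating point: (fpr 1/3, tpr 1)
  expect_true(any(abs(r$roc$fpr - 1 / 3) < 1e-12 & r$roc$tpr == 1))
  expect_equal(nrow(r$roc), 3)  # (0,0) plus one point per tied threshold
})

test_that("the peak-acceleration baseline is the scalar threshold sweep", {
  y <- rep(c("impact", "nonimpact"), each = 10)
  peaks <- c(rep(30, 10), rep(12, 10))
  expect_equal(baseline_threshold_curves(peaks, y)$auc_roc, 1)

  set.seed(151)
  peaks <- rexp(20, 1 / 20)
  b <- baseline_threshold_curves(peaks, y)
  r <- roc_pr_curves(peaks, y)
  expect_identical(b, r)

  # identical class distributions: AUC near 1/2 over label permutations
  set.seed(152)
  aucs <- replicate(50, {
    p <- rnorm(30, 20, 5)
    baseline_threshold_curves(p, sample(rep(c("impact", "nonimpact"),
                                            15)))$auc_roc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("forward selection finds the separating feature, respects ties and stops", {
  set.seed(161)
  n <- 30
  X <- matrix(rnorm(n * 5), ncol = 5)
  colnames(X) <- paste0("f", 1:5)
  y <- rep(c("impact", "nonimpact"), each = n / 2)
  X[, 3] <- X[, 3] + ifelse(y == "impact", 4, -4)  # only f3 separates
  sel <- sequential_forward_selection(X, y, classifier_config())
  expect_equal(sel$features[1], "f3")
  expect_equal(length(sel$features), 1)  # cost 0 cannot strictly improve
  expect_equal(sel$trace$cost[1], 0)

  # two identical perfect features: the lower index wins
  X2 <- cbind(X[, 3], X[, 3], X[, 1])
  colnames(X2) <- c("g1", "g2", "g3")
  sel2 <- sequential_forward_selection(X2, y, classifier_config())
  expect_equal(sel2$features[1], "g1")

  # accepted costs are non-increasing
  set.seed(162)
  X3 <- matrix(rnorm(n * 6), ncol = 6)
  colnames(X3) <- paste0("h", 1:6)
  X3[, 2] <- X3[, 2] + ifelse(y == "impact", 1.2, 0)
  X3[, 5] <- X3[, 5] + ifelse(y == "impact", 0, 1.0)
  sel3 <- sequential_forward_selection(X3, y,
                                       classifier_config(max_features = 4))
  expect_true(all(diff(sel3$trace$cost) <= 0))
  expect_lte(length(sel3$features), 4)
})

test_that("f-measure cost selects features too", {
  set.seed(163)
  n <- 20
  X <- matrix(rnorm(n * 3), ncol = 3)
  colnames(X) <- paste0("f", 1:3)
  y <- rep(c("impact", "nonimpact"), each = n / 2)
  X[, 2] <- X[, 2] + ifelse(y == "impact", 4, -4)
  sel <- sequential_forward_selection(X, y,
                                      classifier_config("f_measure"))
  expect_equal(sel$features[1], "f2")
})
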