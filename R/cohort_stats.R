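#' Two-sided Wilcoxon rank-sum test
#'
#' Unpaired two-sided rank-sum (Mann-Whitney) p-value, with the exact null
#' distribution when the smaller sample has at most 8 observations and the
#' pooled data are tie-free, and the normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param a,b Numeric samples (each nonempty).
#' @return Two-sided p-value in (0, 1].
#' @export
ranksum_test <- function(a, b) {
  if (!length(a) || !length(b))
    stop("input error: both samples must be nonempty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
  min(p, 1)
}

#' Bonferroni screen over the feature family
#'
#' Flags features significant at the family-wise level `family_alpha`
#' divided by the registry size (411 comparisons; 0.05/411 is about
#' 1.22e-4, the commonly quoted "0.0001" threshold is that quantity
#' rounded). The comparison is strict: a p-value exactly at the threshold
#' is not flagged. The family size is part of the method, so a p-value
#' vector of any other length is an error; degenerate features should enter
#' with p = 1.
#'
#' @param pvals Numeric vector of 411 p-values in registry order.
#' @param family_alpha Family-wise error level (default 0.05).
#' @return List: `threshold` (adjusted per-comparison level), `significant`
#'   (logical 411-vector), `n_significant`.
#' @export
bonferroni_screen <- function(pvals, family_alpha = 0.05) {
  if (length(pvals) != 411)
    stop(sprintf("family-size error: expected 411 p-values, got %d",
                 length(pvals)), call. = FALSE)
  thr <- family_alpha / 411
  sig <- pvals < thr
  list(threshold = thr, significant = sig, n_significant = sum(sig))
}

#' Rank-sum screen of every registry feature
#'
#' Runs [ranksum_test()] on impact vs nonimpact distributions of each
#' feature and applies the Bonferroni family correction. Features that are
#' constant across all rows are degenerate and get p = 1.
#'
#' @param dataset A `labeled_dataset` (or any data frame with a `label`
#'   column and the 411 registry feature columns).
#' @param family_alpha Family-wise error level (default 0.05).
#' @return Data frame: `feature`, `block`, `p`, `significant`, `direction`
#'   (sign of the impact-minus-nonimpact median difference).
#' @export
screen_features <- function(dataset, family_alpha = 0.05) {
  reg <- feature_registry()
  imp <- dataset$label == "impact"
  res <- vapply(as.character(reg), function(f) {
    x <- dataset[[f]]
    a <- x[imp]; b <- x[!imp]
    if (length(unique(x)) < 2) return(c(1, 0))
    c(ranksum_test(a, b), sign(stats::median(a) - stats::median(b)))
  }, numeric(2))
  scr <- bonferroni_screen(res[1, ], family_alpha)
  data.frame(feature = as.character(reg), block = registry_blocks(reg),
             p = res[1, ], significant = scr$significant,
             direction = res[2, ], row.names = NULL)
}

#' Principal component analysis of the standardized feature matrix
#'
#' PCA on the zero-mean unit-variance feature matrix: variance-explained
#' fractions (summing to 1), orthonormal loadings, and the top contributing
#' features of each leading component ranked by absolute loading.
#' Zero-variance columns cannot be standardized and are dropped with a
#' warning before the decomposition.
#'
#' @param X Numeric feature matrix (rows = samples, n >= 2).
#' @param n_top How many top contributing features to report per component.
#' @param n_components How many leading components to summarize.
#' @return List: `variance_fraction`, `loadings`, `dropped` (names of
#'   zero-variance columns), `top_features` (list of data frames).
#' @export
pca_variance <- function(X, n_top = 30, n_components = 5) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("PCA needs at least 2 rows", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-variance column(s) before PCA",
                    length(dropped)), call. = FALSE)
    X <- X[, !(colnames(X) %in% dropped), drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$rotation))
  top <- lapply(seq_len(k), function(i) {
    lo <- pc$rotation[, i]
    ord <- order(abs(lo), decreasing = TRUE)[seq_len(min(n_top, length(lo)))]
    data.frame(feature = names(lo)[ord], loading = unname(lo[ord]))
  })
  list(variance_fraction = frac, loadings = pc$rotation,
       dropped = dropped, top_features = top)
}

#' Pairwise Pearson correlation matrix of features
#'
#' Symmetric unit-diagonal correlation matrix. Correlations involving
#' zero-variance columns are undefined and reported as 0, with the
#' offending columns listed in the `degenerate` attribute.
#'
#' @param X Numeric feature matrix (n >= 3 rows).
#' @return Correlation matrix with attribute `degenerate`.
#' @export
pearson_matrix <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("correlation needs at least 3 rows", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  bad <- sds == 0 | !is.finite(sds)
  cm <- suppressWarnings(stats::cor(X))
  cm[bad, ] <- 0
  cm[, bad] <- 0
  diag(cm) <- 1
  structure(cm, degenerate = colnames(X)[bad])
}
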