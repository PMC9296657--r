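# Tumour vs non-tumour classification from imaging features.
# LDA is implemented from its Gaussian definition (class means, pooled
# within-class covariance, class priors) so every intermediate quantity is
# inspectable; tumour is the positive class throughout.

CLASS_LEVELS <- c("non_tumour", "tumour")

check_feature_table <- function(table, features) {
  if (!is.data.frame(table)) stop_config("table must be a data.frame")
  miss <- setdiff(c("region", features), names(table))
  if (length(miss))
    stop_config("missing columns: ", paste(miss, collapse = ", "))
  if (!all(table$region %in% CLASS_LEVELS))
    stop_config("region labels must be in {",
                paste(CLASS_LEVELS, collapse = ", "), "}")
  if (!all(complete.cases(table[features])))
    stop_config("feature columns contain missing values")
  invisible(table)
}

#' Fit a linear discriminant model
#'
#' Gaussian discriminant with shared covariance: class means, pooled
#' within-class covariance (denominator `n - 2`), and class priors taken
#' from class frequencies (default) or set equal. Posteriors follow from
#' the two Gaussian densities; the decision boundary is affine.
#'
#' @param table feature table with a `region` column (`tumour` /
#'   `non_tumour`) and the feature columns.
#' @param features character vector of feature column names.
#' @param prior `"frequency"` (default) or `"equal"`.
#' @return object of class `lda_model`: `means` (2 x p), `cov` (pooled),
#'   `priors`, `features`, `levels`.
#' @export
#' @examples
#' tab <- generate_cohort(cohort_spec(seed = 7))
#' m <- fit_lda(tab, c("max_na_norm", "adc"))
#' table(predict(m, tab)$class, tab$region)
fit_lda <- function(table, features, prior = c("frequency", "equal")) {
  prior <- match.arg(prior)
  check_feature_table(table, features)
  if (length(features) < 1L) stop_config("at least one feature is required")
  x <- as.matrix(table[features])
  g <- factor(table$region, levels = CLASS_LEVELS)
  n_k <- table(g)
  if (any(n_k < 1L))
    stop_config("both classes must be present in the training data")
  if (nrow(x) <= length(features) + 1L)
    stop_config("need more samples than features + 1")
  means <- rbind(colMeans(x[g == CLASS_LEVELS[1], , drop = FALSE]),
                 colMeans(x[g == CLASS_LEVELS[2], , drop = FALSE]))
  rownames(means) <- CLASS_LEVELS
  centred <- x - means[as.integer(g), , drop = FALSE]
  sigma <- crossprod(centred) / (nrow(x) - 2)
  if (!is.finite(rcond(sigma)) || rcond(sigma) < .Machine$double.eps * 100)
    stop_config("pooled covariance is singular (collinear or constant ",
                "features); standardise or drop redundant features")
  priors <- if (prior == "frequency") as.numeric(n_k) / nrow(x)
            else c(0.5, 0.5)
  names(priors) <- CLASS_LEVELS
  structure(list(means = means, cov = sigma, priors = priors,
                 features = features, levels = CLASS_LEVELS,
                 prior_mode = prior),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model>", paste(x$features, collapse = " + "),
      sprintf(" priors %.2f/%.2f\n", x$priors[1], x$priors[2]))
  invisible(x)
}

#' Predict classes and posteriors from an LDA model
#'
#' Evaluates the two Gaussian log-densities with the shared covariance and
#' the class priors; posteriors are their softmax. Posterior ties break
#' toward the larger-prior class, then toward tumour, so predictions are
#' deterministic.
#'
#' @param object an [fit_lda()] model.
#' @param newdata feature table containing the model's feature columns.
#' @param ... unused.
#' @return list: `class` (character), `posterior` (n x 2 matrix summing to
#'   1 by row), `score` (posterior probability of tumour).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop_config("newdata lacks feature columns: ",
                paste(miss, collapse = ", "))
  x <- as.matrix(newdata[object$features])
  if (!all(is.finite(x))) stop_config("features must be finite")
  siginv <- solve(object$cov)
  # log pi_k - (x - mu_k)' Sigma^-1 (x - mu_k) / 2, up to a shared constant
  ll <- vapply(1:2, function(k) {
    dx <- x - matrix(object$means[k, ], nrow(x), ncol(x), byrow = TRUE)
    log(object$priors[k]) - rowSums((dx %*% siginv) * dx) / 2
  }, numeric(nrow(x)))
  ll <- matrix(ll, ncol = 2)
  post <- exp(ll - apply(ll, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- object$levels
  # larger prior first; residual ties resolve toward tumour
  tie_order <- order(-object$priors, c(2L, 1L))
  cls <- apply(post, 1, function(p) {
    top <- which(p == max(p))
    if (length(top) > 1L) top <- intersect(tie_order, top)[1]
    object$levels[top]
  })
  list(class = as.character(cls), posterior = post,
       score = post[, "tumour"])
}

#' Confusion-matrix report for binary tumour classification
#'
#' Tumour is the positive class: sensitivity = TP/(TP+FN) over true tumour
#' rows, specificity = TN/(TN+FP) over true non-tumour rows. When scores
#' are supplied the ROC curve and AUC are included.
#'
#' @param truth,predicted character vectors in
#'   `{tumour, non_tumour}`.
#' @param scores optional numeric scores (higher = more tumour-like).
#' @return object of class `classifier_report`: `accuracy`, `sensitivity`,
#'   `specificity`, `confusion` (named TP/FP/TN/FN), `n`, and when scored,
#'   `roc` and `auc`.
#' @export
classifier_report <- function(truth, predicted, scores = NULL) {
  if (length(truth) != length(predicted))
    stop_config("truth and predicted lengths differ")
  tp <- sum(truth == "tumour" & predicted == "tumour")
  fn <- sum(truth == "tumour" & predicted == "non_tumour")
  tn <- sum(truth == "non_tumour" & predicted == "non_tumour")
  fp <- sum(truth == "non_tumour" & predicted == "tumour")
  rep <- list(accuracy = (tp + tn) / length(truth),
              sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
              specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
              confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
              n = length(truth))
  if (!is.null(scores) && length(unique(truth)) == 2L) {
    ra <- roc_auc(scores, as.integer(truth == "tumour"))
    rep$roc <- ra$roc
    rep$auc <- ra$auc
  }
  structure(rep, class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> acc %.3f sens %.3f spec %.3f (n = %d)",
              x$accuracy, x$sensitivity, x$specificity, x$n))
  if (!is.null(x$auc)) cat(sprintf("  AUC %.3f", x$auc))
  cat("\n")
  invisible(x)
}

#' Leave-one-out cross-validation of an LDA model
#'
#' Refits the model n times with one row held out; each held-out row is
#' scored by the fold's model. Folds whose training split would lose a
#' class entirely are skipped with a warning and excluded from the report.
#'
#' @inheritParams fit_lda
#' @return a [classifier_report()] over the held-out predictions (with ROC
#'   and AUC from the held-out tumour posteriors), plus `n_skipped`.
#' @export
loocv <- function(table, features, prior = c("frequency", "equal")) {
  prior <- match.arg(prior)
  check_feature_table(table, features)
  n <- nrow(table)
  if (n < 4L) stop_config("LOOCV needs at least 4 rows")
  pred <- character(n); score <- numeric(n); ok <- logical(n)
  for (i in seq_len(n)) {
    train <- table[-i, , drop = FALSE]
    if (length(unique(train$region)) < 2L) {
      ok[i] <- FALSE
      next
    }
    m <- fit_lda(train, features, prior)
    p <- predict(m, table[i, , drop = FALSE])
    pred[i] <- p$class; score[i] <- p$score; ok[i] <- TRUE
  }
  if (any(!ok))
    warning(sum(!ok), " LOOCV fold(s) skipped: a training split lost a class")
  rep <- classifier_report(table$region[ok], pred[ok], score[ok])
  rep$n_skipped <- sum(!ok)
  rep
}

#' Evaluate a fitted LDA model on an independent test set
#'
#' @param model an [fit_lda()] model.
#' @param test_table feature table with the model's features and true
#'   `region` labels.
#' @return a [classifier_report()] (tumour positive) with ROC and AUC.
#' @export
evaluate_on_test <- function(model, test_table) {
  stopifnot(inherits(model, "lda_model"))
  check_feature_table(test_table, model$features)
  p <- predict(model, test_table)
  classifier_report(test_table$region, p$class, p$score)
}

#' ROC curve and AUC
#'
#' Sweeps every threshold over the scores (classifying `score >= t` as
#' positive) and integrates by the trapezoid rule, which equals the
#' Mann-Whitney pair-win fraction with ties counted one half.
#'
#' @param scores numeric; higher means more positive-like.
#' @param labels 0/1, logical, or `{tumour, non_tumour}` labels.
#' @return list: `roc` (`data.frame` of `threshold`, `fpr`, `tpr`,
#'   monotone from (0,0) to (1,1)) and `auc`.
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc # 0.75
roc_auc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "tumour")
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop_config("scores and labels lengths differ")
  if (!all(labels %in% 0:1) || length(unique(labels)) < 2L)
    stop_config("both classes must be present")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / np,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / nn,
                numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Principal component analysis of imaging features
#'
#' Centred PCA via the spectral decomposition of the covariance (or, by
#' default, the correlation, since the features mix dimensionless signal
#' and mm^2/s) matrix, computed by [stats::prcomp()]. Loadings are signed
#' deterministically: the first nonzero entry of each component is
#' positive.
#'
#' @param table feature table.
#' @param features feature column names (>= 2; >= 3 rows).
#' @param scale standardise features (correlation PCA, default `TRUE`).
#' @return object of class `pca_result`: `loadings` (p x p, orthonormal
#'   columns), `var_fraction`, `scores` (n x p), `sdev`.
#' @export
pca_features <- function(table, features, scale = TRUE) {
  if (length(features) < 2L) stop_config("need at least 2 features")
  x <- as.matrix(table[features])
  if (nrow(x) < 3L) stop_config("need at least 3 samples")
  if (scale && any(apply(x, 2, sd) == 0))
    stop_config("zero-variance feature under correlation scaling")
  p <- prcomp(x, center = TRUE, scale. = scale)
  flip <- apply(p$rotation, 2, function(v) {
    nz <- which(abs(v) > .Machine$double.eps^0.5)[1]
    if (is.na(nz) || v[nz] >= 0) 1 else -1
  })
  loadings <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)
  structure(list(loadings = loadings,
                 var_fraction = p$sdev^2 / sum(p$sdev^2),
                 scores = scores, sdev = p$sdev, scaled = scale),
            class = "pca_result")
}

#' Gaussian concentration ellipse for a score cloud
#'
#' Covariance-based ellipse containing the stated probability mass under a
#' bivariate Gaussian fitted to the points (this is the classical
#' covariance ellipse, not a kernel density contour).
#'
#' @param x,y coordinates (e.g. the first two PC scores of one class).
#' @param level probability mass (default 0.95).
#' @param n_points polygon resolution.
#' @return `data.frame` of ellipse boundary coordinates `x`, `y`.
#' @export
concentration_ellipse <- function(x, y, level = 0.95, n_points = 100L) {
  if (length(x) < 3L) stop_config("need at least 3 points")
  ctr <- c(mean(x), mean(y))
  sig <- cov(cbind(x, y))
  r <- sqrt(qchisq(level, df = 2))
  ang <- seq(0, 2 * pi, length.out = n_points)
  circ <- rbind(cos(ang), sin(ang)) * r
  ell <- t(chol(sig)) %*% circ + ctr
  data.frame(x = ell[1, ], y = ell[2, ])
}
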