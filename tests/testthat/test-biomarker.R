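# LDA classifier, LOOCV, test-set evaluation, ROC/AUC, PCA

make_table <- function(x, region, feature = "f") {
  d <- data.frame(region = region)
  if (is.matrix(x)) for (j in seq_len(ncol(x))) d[[feature[j]]] <- x[, j]
  else d[[feature]] <- x
  d
}

test_that("1-D equal-variance LDA puts the boundary at the midpoint", {
  set.seed(1)
  tab <- make_table(c(rnorm(2000, 0), rnorm(2000, 10)),
                    rep(c("non_tumour", "tumour"), each = 2000))
  m <- fit_lda(tab, "f")
  # equal priors and shared variance: boundary = (mu1 + mu2)/2
  boundary <- uniroot(function(x)
    predict(m, data.frame(f = x))$score - 0.5, c(2, 8))$root
  expect_equal(boundary, 5, tolerance = 0.15)
})

test_that("posteriors sum to one and duplicate features are rejected", {
  tab <- generate_cohort(cohort_spec(seed = 2L))
  m <- fit_lda(tab, c("max_na_norm", "adc"))
  p <- predict(m, tab)
  expect_equal(unname(rowSums(p$posterior)), rep(1, nrow(tab)))
  tab$dup <- tab$max_na_norm
  expect_error(fit_lda(tab, c("max_na_norm", "dup")), "singular")
})

test_that("predictions match an independent Gaussian-discriminant oracle", {
  toy <- data.frame(
    region = c("tumour", "tumour", "tumour",
               "non_tumour", "non_tumour", "non_tumour"),
    f1 = c(2.1, 2.5, 1.9, 0.8, 1.0, 0.7),
    f2 = c(0.6, 0.8, 0.9, 1.5, 1.8, 1.4))
  m <- fit_lda(toy, c("f1", "f2"))
  p <- predict(m, toy)
  o <- oracle_lda_predict(toy, toy, c("f1", "f2"))
  expect_identical(p$class, o$class)
  expect_equal(unname(p$posterior), unname(o$posterior), tolerance = 1e-10)
  # and on random data, against MASS::lda as an external reference
  skip_if_not_installed("MASS")
  set.seed(7)
  tab <- generate_cohort(cohort_spec(seed = 7L))
  feats <- c("max_na_norm", "mean_na_norm", "adc")
  m2 <- fit_lda(tab, feats)
  ml <- MASS::lda(region ~ max_na_norm + mean_na_norm + adc, tab)
  pm <- predict(ml, tab)
  p2 <- predict(m2, tab)
  expect_identical(p2$class, as.character(pm$class))
  expect_equal(unname(p2$posterior[, "tumour"]),
               unname(pm$posterior[, "tumour"]), tolerance = 1e-8)
})

test_that("parameters are recovered from data generated at known values", {
  sp <- cohort_spec(n_per_class = 1000L, seed = 13L)
  tab <- generate_cohort(sp)
  feats <- c("max_na_norm", "mean_na_norm", "adc")
  m <- fit_lda(tab, feats)
  for (cl in c("tumour", "non_tumour")) {
    se <- sp$class_sds[cl, ] / sqrt(1000)
    expect_true(all(abs(m$means[cl, ] - sp$class_means[cl, ]) <= 3 * se))
  }
  # pooled covariance within 10% Frobenius of the class-average truth
  truth <- Reduce(`+`, lapply(c("tumour", "non_tumour"), function(cl) {
    d <- diag(sp$class_sds[cl, ])
    d %*% sp$class_cor %*% d
  })) / 2
  expect_lt(norm(m$cov - truth, "F") / norm(truth, "F"), 0.10)
})

test_that("LOOCV is perfect on well-separated classes and matches
           exhaustive enumeration on a 4-point layout", {
  set.seed(3)
  tab <- make_table(c(rnorm(20, 0, 0.1), rnorm(20, 50, 0.1)),
                    rep(c("non_tumour", "tumour"), each = 20))
  expect_equal(loocv(tab, "f")$accuracy, 1)

  # interleaved 1-D layout whose held-out predictions are not all correct
  four <- data.frame(region = c("tumour", "tumour",
                                "non_tumour", "non_tumour"),
                     f = c(0, 1, 0.45, 0.8))
  # oracle: enumerate the four folds with the independent discriminant
  oracle_pred <- vapply(1:4, function(i)
    oracle_lda_predict(four[-i, ], four[i, , drop = FALSE], "f")$class,
    character(1))
  rep4 <- loocv(four, "f")
  expect_equal(rep4$accuracy, mean(oracle_pred == four$region))
})

test_that("test-set evaluation mirrors resubstitution and label symmetry", {
  set.seed(4)
  tab <- make_table(c(rnorm(15, 0, 0.2), rnorm(15, 8, 0.2)),
                    rep(c("non_tumour", "tumour"), each = 15))
  m <- fit_lda(tab, "f")
  r_test <- evaluate_on_test(m, tab)
  r_resub <- classifier_report(tab$region, predict(m, tab)$class)
  expect_identical(r_test$confusion, r_resub$confusion)
  expect_equal(r_test$accuracy, 1)
  # swapping the test labels swaps sensitivity and specificity
  swapped <- tab
  swapped$region <- ifelse(tab$region == "tumour", "non_tumour", "tumour")
  r_swap <- evaluate_on_test(m, swapped)
  expect_equal(r_swap$sensitivity, 1 - r_test$specificity + 0)
  expect_equal(r_swap$specificity, 1 - r_test$sensitivity + 0)
  expect_error(evaluate_on_test(m, data.frame(region = "tumour", g = 1)),
               "missing columns|lacks")
})

test_that("AUC equals the pair-counting oracle, exhaustively to n = 6", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 0, 0, 1, 1, 1))$auc, 0.5)
  set.seed(5)
  for (n in 2:6) {
    score_sets <- list(runif(n), sample(c(0.2, 0.4, 0.4, 0.7), n, TRUE))
    for (scores in score_sets) {
      for (mask in 1:(2^n - 2)) {       # every labelling with both classes
        labels <- as.integer(intToBits(mask))[1:n]
        out <- roc_auc(scores, labels)
        expect_equal(out$auc, oracle_auc(scores, labels), tolerance = 1e-12)
        expect_true(all(diff(out$roc$fpr) >= 0) && all(diff(out$roc$tpr) >= 0))
      }
    }
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(6)
  scores <- rnorm(40); labels <- rbinom(40, 1, 0.5)
  labels[1:2] <- c(0, 1)
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a0)
  expect_equal(roc_auc(2 * scores + 17, labels)$auc, a0)
  expect_error(roc_auc(scores, rep(1, 40)), "both classes")
})

test_that("LOOCV accuracy approaches test accuracy as n grows", {
  gaps <- sapply(c(30L, 300L), function(n) {
    tr <- generate_cohort(cohort_spec(n_per_class = n, seed = 21L))
    te <- generate_cohort(cohort_spec(n_per_class = 500L, seed = 22L))
    feats <- c("max_na_norm", "adc")
    cv <- loocv(tr, feats)$accuracy
    ts <- evaluate_on_test(fit_lda(tr, feats), te)$accuracy
    abs(cv - ts)
  })
  expect_lt(gaps[2], gaps[1] + 0.05)
  expect_lt(gaps[2], 0.05)
})

test_that("PCA matches closed forms and fixes loading signs", {
  # collinear features: one component carries all variance
  tab <- data.frame(f1 = 1:10, f2 = 2 * (1:10) + 3)
  p <- pca_features(tab, c("f1", "f2"), scale = TRUE)
  expect_equal(p$var_fraction[1], 1, tolerance = 1e-12)
  # eigenvalues of a 2x2 correlation matrix are 1 + r and 1 - r
  set.seed(8)
  z <- matrix(rnorm(4000), 2000, 2)
  x <- cbind(z[, 1], 0.6 * z[, 1] + sqrt(1 - 0.36) * z[, 2])
  tab2 <- data.frame(f1 = x[, 1], f2 = x[, 2])
  r <- cor(tab2$f1, tab2$f2)
  p2 <- pca_features(tab2, c("f1", "f2"), scale = TRUE)
  expect_equal(sort(p2$sdev^2, decreasing = TRUE), c(1 + r, 1 - r),
               tolerance = 1e-10)
  # deterministic signs: first nonzero loading entry positive; orthonormal
  expect_true(all(apply(p2$loadings, 2, function(v) v[which(v != 0)[1]] > 0)))
  expect_equal(unname(crossprod(p2$loadings)), diag(2), tolerance = 1e-12)
  # anti-correlated features load PC1 in opposing directions
  tabn <- generate_cohort(cohort_spec(seed = 10L))
  pn <- pca_features(tabn, c("max_na_norm", "adc"))
  expect_lt(prod(pn$loadings[, 1]), 0)
  expect_equal(sum(pn$var_fraction), 1, tolerance = 1e-12)
  expect_error(pca_features(data.frame(a = c(1, 1, 1), b = 1:3),
                            c("a", "b")), "zero-variance")
})

test_that("concentration ellipses cover about their nominal mass", {
  set.seed(9)
  x <- rnorm(4000); y <- rnorm(4000)
  ell <- concentration_ellipse(x, y, level = 0.95)
  # mahalanobis containment fraction close to 0.95
  s <- solve(cov(cbind(x, y)))
  d2 <- rowSums((cbind(x - mean(x), y - mean(y)) %*% s) *
                  cbind(x - mean(x), y - mean(y)))
  expect_equal(mean(d2 <= qchisq(0.95, 2)), 0.95, tolerance = 0.02)
  # the polygon's extreme mahalanobis radius equals the chi-square bound
  de <- cbind(ell$x - mean(x), ell$y - mean(y))
  expect_equal(max(rowSums((de %*% s) * de)), qchisq(0.95, 2),
               tolerance = 0.05)
})
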