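# shared fixture builders for the test suite (everything is generated in
# code; no stored data)

# small noise-free sodium scene with a uniform tumour
quiet_scene_spec <- function(...) {
  scene_phantom_spec(noise_sigma = 0, tumour_conc_heterogeneity_sd = 0, ...)
}

# dwi_series of spatially constant volumes with given per-b signals
constant_series <- function(b_values, signals, shape = c(4L, 4L, 2L)) {
  vols <- lapply(signals, function(s)
    image_volume(array(s, dim = shape), c(1, 1, 1), "dwi"))
  dwi_series(vols, b_values)
}

# independent LDA oracle: literal Gaussian discriminant evaluation,
# sharing no code with fit_lda/predict
oracle_lda_predict <- function(train, test, features,
                               prior = c("frequency", "equal")) {
  prior <- match.arg(prior)
  lv <- c("non_tumour", "tumour")
  xtr <- as.matrix(train[features]); xte <- as.matrix(test[features])
  mu <- lapply(lv, function(l) colMeans(xtr[train$region == l, , drop = FALSE]))
  pooled <- Reduce(`+`, lapply(seq_along(lv), function(k) {
    xs <- xtr[train$region == lv[k], , drop = FALSE]
    if (nrow(xs) < 2) return(matrix(0, length(features), length(features)))
    (nrow(xs) - 1) * stats::cov(xs)
  })) / (nrow(xtr) - 2)
  pk <- if (prior == "equal") c(0.5, 0.5) else
    c(mean(train$region == lv[1]), mean(train$region == lv[2]))
  si <- solve(pooled)
  ll <- sapply(1:2, function(k) {
    apply(xte, 1, function(x)
      log(pk[k]) - 0.5 * t(x - mu[[k]]) %*% si %*% (x - mu[[k]]))
  })
  ll <- matrix(ll, ncol = 2)
  post <- exp(ll - apply(ll, 1, max)); post <- post / rowSums(post)
  list(class = lv[max.col(post, ties.method = "last")], posterior = post)
}

# independent AUC oracle: pair counting with ties worth one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# numeric-integration oracle for the Rician mean; exponents combined with
# the scaled Bessel so the integrand is stable at high SNR:
# x * f(x) = x^2/sigma^2 * exp(-(x - A)^2 / (2 sigma^2)) * I0e(xA/sigma^2)
oracle_rician_mean <- function(A, sigma) {
  stats::integrate(function(x)
    x^2 / sigma^2 * exp(-(x - A)^2 / (2 * sigma^2)) *
      besselI(x * A / sigma^2, 0, expon.scaled = TRUE),
    0, A + 20 * sigma, rel.tol = 1e-10)$value
}
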