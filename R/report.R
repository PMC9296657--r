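# Group-level statistics used throughout the figures: pooled-variance
# Student t comparisons, Pearson correlation, fold-change summaries.
# The t and correlation machinery is stats::t.test / stats::cor.test; this
# module adds the degenerate-case conventions and the reporting layout
# (n, mean +/- SEM, fold change).

#' Compare two groups with an unpaired Student t test
#'
#' Pooled-variance (Student) two-tailed t test by default, Welch by flag.
#' Degenerate inputs follow explicit conventions: zero pooled variance with
#' equal means gives t = 0, p = 1; with unequal means the comparison is
#' flagged degenerate (infinite t, p = 0).
#'
#' Fold change is reported as relative change `(mean_a - mean_b)/mean_b`
#' (so +2.5 reads "2.5-fold increase", -0.7 "0.7-fold lower"); `NA` when
#' `mean_b` is 0.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param a_name,b_name group labels for the report.
#' @param welch use the Welch (unequal-variance) test instead.
#' @return object of class `group_comparison`: `groups`, `n`, `means`,
#'   `sem`, `t`, `df`, `p`, `fold_change`, `degenerate`, `method`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))
compare_groups <- function(a, b, a_name = "a", b_name = "b",
                           welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop_config("each group needs at least 2 values")
  if (anyNA(a) || anyNA(b)) stop_config("missing values are not allowed")
  means <- c(mean(a), mean(b))
  sems <- c(sd(a) / sqrt(length(a)), sd(b) / sqrt(length(b)))
  degenerate <- FALSE
  if (sd(a) == 0 && sd(b) == 0) {
    if (means[1] == means[2]) {
      tt <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                 p.value = 1)
    } else {
      tt <- list(statistic = sign(means[1] - means[2]) * Inf,
                 parameter = length(a) + length(b) - 2, p.value = 0)
      degenerate <- TRUE
    }
  } else {
    tt <- t.test(a, b, var.equal = !welch)
  }
  structure(list(groups = c(a_name, b_name),
                 n = c(length(a), length(b)),
                 means = setNames(means, c(a_name, b_name)),
                 sem = setNames(sems, c(a_name, b_name)),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 fold_change = if (means[2] != 0)
                   fold_change(means[1], means[2]) else NA_real_,
                 degenerate = degenerate,
                 method = if (welch) "welch" else "student"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s (n=%d, %.3g+/-%.3g) vs %s (n=%d, %.3g+/-%.3g): t(%.3g) = %.3f, p = %.3g\n",
    x$groups[1], x$n[1], x$means[1], x$sem[1],
    x$groups[2], x$n[2], x$means[2], x$sem[2], x$df, x$t, x$p))
  invisible(x)
}

#' Pearson correlation with two-tailed p value
#'
#' `stats::cor.test` (Pearson), with the zero-variance precondition made
#' explicit.
#'
#' @param x,y numeric vectors, n >= 3, both with nonzero variance.
#' @return object of class `correlation_result`: `r`, `n`, `p`.
#' @export
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$r # 0.6
pearson_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_config("x and y lengths differ")
  if (length(x) < 3L) stop_config("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop_config("missing values are not allowed")
  if (sd(x) == 0 || sd(y) == 0)
    stop_config("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), n = length(x), p = ct$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f (n = %d, p = %.3g)\n",
              x$r, x$n, x$p))
  invisible(x)
}

#' Relative fold change
#'
#' `(a - b)/b`: +2.5 means a 2.5-fold increase over the comparator, -0.7 a
#' 0.7-fold decrease.
#'
#' @param mean_a,mean_b group means; `mean_b` must be nonzero.
#' @return relative change, dimensionless.
#' @export
fold_change <- function(mean_a, mean_b) {
  check_scalar(mean_a, "mean_a")
  check_scalar(mean_b, "mean_b")
  if (mean_b == 0) stop_config("comparator mean is zero")
  (mean_a - mean_b) / mean_b
}
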