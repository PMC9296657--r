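# Apparent diffusion coefficient estimation from multi-b DWI series.
# The two-point closed form ADC = -ln(S/S0)/b generalises to an ordinary
# least-squares fit of ln S on b when more than two b-values are available;
# the two agree exactly for two b-values.

#' Diffusion-weighted series container
#'
#' Orders volumes by b-value and validates: distinct b-values, exactly one
#' b = 0 (the S0 / A0 volume), all volumes on one grid.
#'
#' @param volumes list of [image_volume()]s.
#' @param b_values numeric, s/mm^2, parallel to `volumes`.
#' @return an object of class `dwi_series`.
#' @export
dwi_series <- function(volumes, b_values) {
  b_values <- as.numeric(b_values)
  if (length(volumes) != length(b_values))
    stop_config("one b-value per volume is required")
  if (anyDuplicated(b_values) || any(b_values < 0))
    stop_config("b-values must be distinct and non-negative")
  if (sum(b_values == 0) != 1L)
    stop_config("exactly one b = 0 volume is required")
  ref <- dim(volumes[[1]]$data)
  for (v in volumes) {
    stopifnot(inherits(v, "image_volume"))
    if (!identical(dim(v$data), ref))
      stop_config("all volumes must share one grid")
  }
  o <- order(b_values)
  structure(list(volumes = volumes[o], b_values = b_values[o]),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat("<dwi_series> b =", paste(x$b_values, collapse = ", "), "s/mm^2 on",
      paste(dim(x$volumes[[1]]$data), collapse = "x"), "voxels\n")
  invisible(x)
}

# OLS slope of y on x (x of length >= 2, distinct values)
ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' ROI-level apparent diffusion coefficient
#'
#' Averages the signal over the mask at each b-value, then estimates the
#' ADC: with exactly two b-values, the closed form `-ln(S/S0)/b`; with more,
#' minus the OLS slope of `ln S(b)` on `b` (default), or the mean of all
#' pairwise two-point ADCs (`method = "pairwise"`, emitted in either case
#' for audit).
#'
#' @param series a [dwi_series()].
#' @param mask logical array on the series grid.
#' @param method `"ols"` (default) or `"pairwise"`.
#' @param noise_floor signals at or below this level are excluded from the
#'   fit (set to about 3x the background noise SD to avoid noise-floor
#'   bias); default 0 (no exclusion beyond positivity).
#' @return list of class `adc_result`: `scope = "roi"`, `adc` (mm^2/s),
#'   `residual` (RSS of the log-linear fit), `b_values`, `mean_signal`,
#'   `pairwise` (data.frame of per-pair ADCs).
#' @export
#' @examples
#' sc <- generate_dwi_series(dwi_scene_spec())
#' compute_adc_roi(sc$series, sc$rois$masks$tumour)
compute_adc_roi <- function(series, mask, method = c("ols", "pairwise"),
                            noise_floor = 0) {
  method <- match.arg(method)
  stopifnot(inherits(series, "dwi_series"))
  if (!is.logical(mask) ||
      !identical(dim(mask), dim(series$volumes[[1]]$data)))
    stop_config("mask must be logical on the series grid")
  if (!any(mask)) stop_config("mask is empty")
  s_mean <- vapply(series$volumes, function(v) mean(v$data[mask]),
                   numeric(1))
  b <- series$b_values
  keep <- s_mean > max(noise_floor, 0)
  if (any(!keep) && noise_floor <= 0)
    stop_config("non-positive mean ROI signal at b = ",
                paste(b[!keep], collapse = ", "),
                "; data are at the noise floor")
  b_use <- b[keep]; s_use <- s_mean[keep]
  if (length(b_use) < 2L)
    stop_config("fewer than two usable b-values; cannot fit a decay")
  pairs <- utils::combn(seq_along(b_use), 2)
  pairwise <- data.frame(
    b_low = b_use[pairs[1, ]], b_high = b_use[pairs[2, ]],
    adc = -(log(s_use[pairs[2, ]]) - log(s_use[pairs[1, ]])) /
      (b_use[pairs[2, ]] - b_use[pairs[1, ]]))
  adc <- if (method == "ols") -ols_slope(b_use, log(s_use))
         else mean(pairwise$adc)
  fit <- log(s_use) - mean(log(s_use)) + adc * (b_use - mean(b_use))
  structure(list(scope = "roi", adc = adc, residual = sum(fit^2),
                 b_values = b_use, mean_signal = s_use,
                 method = method, pairwise = pairwise),
            class = "adc_result")
}

#' Voxelwise apparent diffusion coefficient map
#'
#' Log-linear OLS fit per voxel across the series. Voxels with any signal
#' at or below `max(noise_floor, 0)` are marked invalid (`NA` in the map)
#' rather than erroring; the invalid fraction is reported.
#'
#' @param series a [dwi_series()].
#' @param noise_floor exclusion threshold as in [compute_adc_roi()], applied
#'   voxelwise; a voxel is invalid if any of its signals fall at or below it.
#' @return list of class `adc_result`: `scope = "map"`, `adc` (array,
#'   mm^2/s, `NA` where invalid), `residual` (per-voxel RSS array),
#'   `invalid_fraction`, `b_values`.
#' @export
compute_adc_map <- function(series, noise_floor = 0) {
  stopifnot(inherits(series, "dwi_series"))
  b <- series$b_values
  d <- dim(series$volumes[[1]]$data)
  S <- vapply(series$volumes, function(v) as.numeric(v$data),
              numeric(prod(d)))
  valid <- rowSums(S <= max(noise_floor, 0)) == 0
  lnS <- log(S[valid, , drop = FALSE])
  bc <- b - mean(b)
  slope <- as.numeric(lnS %*% bc) / sum(bc^2)
  resid <- lnS - rowMeans(lnS) - outer(slope, bc)
  adc <- rep(NA_real_, prod(d)); adc[valid] <- -slope
  rss <- rep(NA_real_, prod(d)); rss[valid] <- rowSums(resid^2)
  structure(list(scope = "map", adc = array(adc, dim = d),
                 residual = array(rss, dim = d),
                 invalid_fraction = mean(!valid), b_values = b),
            class = "adc_result")
}

#' @export
print.adc_result <- function(x, ...) {
  if (x$scope == "roi")
    cat(sprintf("<adc_result roi> ADC = %.4g mm^2/s (%s over b = %s)\n",
                x$adc, x$method, paste(x$b_values, collapse = ", ")))
  else
    cat(sprintf("<adc_result map> median ADC = %.4g mm^2/s, %.1f%% invalid\n",
                stats::median(x$adc, na.rm = TRUE),
                100 * x$invalid_fraction))
  invisible(x)
}

#' Summarise an ADC map over an ROI
#'
#' Mean and median of valid map voxels inside a mask; invalid voxels are
#' excluded and counted.
#'
#' @param adc_map an `adc_result` from [compute_adc_map()].
#' @param mask logical array on the map grid.
#' @return list (`mean`, `median`, `n_valid`, `n_invalid`).
#' @export
summarise_adc <- function(adc_map, mask) {
  stopifnot(inherits(adc_map, "adc_result"), adc_map$scope == "map")
  v <- adc_map$adc[mask]
  list(mean = mean(v, na.rm = TRUE), median = stats::median(v, na.rm = TRUE),
       n_valid = sum(!is.na(v)), n_invalid = sum(is.na(v)))
}
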