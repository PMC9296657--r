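# Sodium image quantification: B1 (1/r^2) correction, ROI statistics,
# phantom normalisation to concentration, ROI / calliper volume estimates.

#' Correct a sodium image for surface-coil B1 inhomogeneity
#'
#' Fits the radial gain model \eqn{g(x) = G / (d(x) + d_0)^2}, with
#' \eqn{d(x)} the distance to the coil origin, to a uniform-phantom
#' reference image, then divides the target image by the fitted gain map
#' (normalised to unit mean, so overall image scale is preserved and the
#' reference's absolute intensity cancels).
#'
#' The fit minimises squared error in log-signal space by default, which is
#' robust to the large dynamic range of a concentrated reference phantom;
#' `log_space = FALSE` fits in plain signal space. The only nonlinear
#' parameter is \eqn{d_0}, profiled by a 1-D search with \eqn{G} solved
#' exactly at each candidate. A reference with negligible spatial variation
#' (coefficient of variation below `flat_tol`) is treated as a volume-coil
#' acquisition and the image is returned unchanged.
#'
#' @param image the [image_volume()] to correct.
#' @param reference uniform-phantom [image_volume()] on the same grid,
#'   acquired with the same coil.
#' @param coil_origin coil position, mm.
#' @param log_space fit in log-signal space (default) or plain space.
#' @param d0_range search interval (mm) for the gain-floor distance.
#' @param flat_tol reference CV below which the correction is the identity.
#' @return list with `image` (corrected [image_volume()]) and `b1` (list:
#'   `coil_origin`, `d0`, `G`, `gain_map` (unit mean), `flat`).
#' @export
b1_correct <- function(image, reference, coil_origin,
                       log_space = TRUE, d0_range = c(0.25, 100),
                       flat_tol = 1e-6) {
  stopifnot(inherits(image, "image_volume"),
            inherits(reference, "image_volume"))
  if (!identical(dim(image$data), dim(reference$data)))
    stop_config("image and reference grids differ")
  s <- as.numeric(reference$data)
  if (all(s <= 0)) stop_config("reference image is non-positive everywhere")
  cv <- if (length(s) > 1) sd(s) / mean(s) else 0
  if (cv < flat_tol) {
    b1 <- list(coil_origin = as.numeric(coil_origin), d0 = Inf, G = mean(s),
               gain_map = array(1, dim = dim(image$data)), flat = TRUE)
    return(list(image = image, b1 = b1))
  }
  d <- as.numeric(distance_map(dim(image$data), image$spacing, coil_origin))
  if (max(d) - min(d) < sqrt(.Machine$double.eps))
    stop_config("degenerate geometry: all voxels equidistant from the coil")
  use <- s > 0
  if (log_space) {
    ls <- log(s[use]); du <- d[use]
    rss <- function(d0) {
      r <- ls + 2 * log(du + d0)
      sum((r - mean(r))^2)
    }
  } else {
    su <- s[use]; du <- d[use]
    rss <- function(d0) {
      g1 <- 1 / (du + d0)^2
      G <- sum(su * g1) / sum(g1^2)
      sum((su - G * g1)^2)
    }
  }
  opt <- optimize(rss, d0_range, tol = 1e-10)
  d0 <- opt$minimum
  if (log_space) {
    G <- exp(mean(log(s[use]) + 2 * log(d[use] + d0)))
  } else {
    g1 <- 1 / (d[use] + d0)^2
    G <- sum(s[use] * g1) / sum(g1^2)
  }
  if (G <= 0) stop_config("fitted gain is non-positive")
  gain <- G / (d + d0)^2
  gain <- gain / mean(gain)
  corrected <- image_volume(array(as.numeric(image$data) / gain,
                                  dim = dim(image$data)),
                            image$spacing, image$modality,
                            meta = c(image$meta, list(b1_corrected = TRUE)))
  list(image = corrected,
       b1 = list(coil_origin = as.numeric(coil_origin), d0 = d0, G = G,
                 gain_map = array(gain, dim = dim(image$data)), flat = FALSE))
}

#' Raw per-ROI signal statistics
#'
#' Arithmetic mean, maximum and voxel count of the image inside each mask of
#' an [roi_set()]. The maximum is taken on the image as supplied (corrected
#' but unsmoothed in the standard pipeline); apply [median_filter3()] first
#' if a noise-robust maximum is wanted.
#'
#' @param image an [image_volume()].
#' @param rois an [roi_set()] on the same grid.
#' @return `data.frame` with columns `roi`, `mean_raw`, `max_raw`, `n_vox`.
#' @export
roi_stats <- function(image, rois) {
  stopifnot(inherits(image, "image_volume"), inherits(rois, "roi_set"))
  if (!identical(dim(image$data), rois$grid_shape))
    stop_config("image and ROI grids differ")
  out <- lapply(names(rois$masks), function(nm) {
    v <- image$data[rois$masks[[nm]]]
    if (length(v) == 0L) stop_config("ROI '", nm, "' is empty")
    data.frame(roi = nm, mean_raw = mean(v), max_raw = max(v),
               n_vox = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Normalise ROI statistics to the reference phantom
#'
#' Divides mean and maximum raw signals by the phantom ROI mean and scales
#' by the phantom concentration, converting normalised signal to an apparent
#' tissue sodium concentration. Because differential relaxation is not
#' modelled, the mM columns are phantom-referenced apparent concentrations,
#' exact when signal is concentration-proportional.
#'
#' @param stats `data.frame` from [roi_stats()].
#' @param phantom_stats optional single-row `data.frame` of phantom
#'   statistics; by default the row of `stats` whose `roi` equals
#'   `phantom_roi`.
#' @param phantom_conc phantom concentration, mM (default 50).
#' @param phantom_roi name of the phantom row in `stats`.
#' @return `stats` with added columns `mean_norm`, `max_norm`, `mean_mM`,
#'   `max_mM`.
#' @export
normalize_to_phantom <- function(stats, phantom_stats = NULL,
                                 phantom_conc = 50,
                                 phantom_roi = "phantom") {
  check_scalar(phantom_conc, "phantom_conc", lower = 0)
  if (is.null(phantom_stats)) {
    hit <- stats$roi == phantom_roi
    if (!any(hit)) stop_config("no ROI named '", phantom_roi, "' in stats")
    phantom_stats <- stats[hit, , drop = FALSE]
  }
  ref <- phantom_stats$mean_raw[1]
  if (!is.finite(ref) || ref <= 0)
    stop_config("phantom mean signal must be positive")
  stats$mean_norm <- stats$mean_raw / ref
  stats$max_norm <- stats$max_raw / ref
  stats$mean_mM <- stats$mean_norm * phantom_conc
  stats$max_mM <- stats$max_norm * phantom_conc
  stats
}

#' 3-D median filter
#'
#' Optional pre-smoothing for the noise-sensitive maximum statistic; off by
#' default everywhere in the pipeline.
#'
#' @param image an [image_volume()].
#' @param radius neighbourhood half-width in voxels (1 gives 3x3x3).
#' @return a filtered [image_volume()].
#' @export
median_filter3 <- function(image, radius = 1L) {
  stopifnot(inherits(image, "image_volume"))
  d <- dim(image$data)
  off <- expand.grid(i = -radius:radius, j = -radius:radius,
                     k = -radius:radius)
  idx <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  stack <- vapply(seq_len(nrow(off)), function(o) {
    ii <- pmin(pmax(idx$i + off$i[o], 1L), d[1])
    jj <- pmin(pmax(idx$j + off$j[o], 1L), d[2])
    kk <- pmin(pmax(idx$k + off$k[o], 1L), d[3])
    image$data[cbind(ii, jj, kk)]
  }, numeric(nrow(idx)))
  out <- apply(stack, 1, stats::median)
  image_volume(array(out, dim = d), image$spacing, image$modality,
               meta = c(image$meta, list(median_filtered = radius)))
}

#' Tumour volume from an ROI mask
#'
#' Voxel count times voxel volume.
#'
#' @param mask logical array.
#' @param spacing mm per voxel, length 3.
#' @return list (`source = "roi"`, `volume` in mm^3, `n_vox`).
#' @export
roi_volume <- function(mask, spacing) {
  if (!is.logical(mask)) stop_config("mask must be logical")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_config("spacing must be three positive values")
  list(source = "roi", volume = sum(mask) * prod(spacing), n_vox = sum(mask))
}

#' Tumour volume from calliper measurements
#'
#' Modified ellipsoidal formula `volume = 1/2 * length * width^2`. The two
#' measurements are sorted so that length is the longer axis; mislabelled
#' inputs are therefore corrected rather than rejected.
#'
#' @param length,width calliper measurements, mm (>= 0).
#' @return list (`source = "calliper"`, `volume` in mm^3, `length`, `width`).
#' @export
#' @examples
#' ellipsoid_volume(10, 8) # 320 mm^3
ellipsoid_volume <- function(length, width) {
  check_scalar(length, "length", lower = 0)
  check_scalar(width, "width", lower = 0)
  ax <- sort(c(length, width), decreasing = TRUE)
  list(source = "calliper", volume = 0.5 * ax[1] * ax[2]^2,
       length = ax[1], width = ax[2])
}
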