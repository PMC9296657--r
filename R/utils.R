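# internal helpers: argument checking, Rician sampling, small numerics

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("natremri_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(name, " must be a finite numeric scalar")
  if (x < lower || x > upper)
    stop_config(name, " must be in [", lower, ", ", upper, "]")
  invisible(x)
}

#' Draw Rician-distributed magnitudes
#'
#' Samples the magnitude-image noise model of MR: the modulus of a complex
#' Gaussian deviate centred on the true signal, `sqrt((A + s*z1)^2 + (s*z2)^2)`
#' with independent standard normal `z1`, `z2`. With `sigma = 0` the true
#' signal is returned unchanged.
#'
#' @param n number of draws; if `A` is longer than `n`, one draw per element
#'   of `A` is returned.
#' @param A true (noise-free) signal amplitude, recycled against `n`.
#' @param sigma noise standard deviation of each Gaussian channel.
#' @return numeric vector of non-negative magnitudes.
#' @seealso [rician_mean()] for the analytic mean of this distribution.
#' @export
#' @examples
#' set.seed(1)
#' mean(rrice(1e4, A = 20, sigma = 1)) # close to 20 at high SNR
rrice <- function(n, A, sigma) {
  check_scalar(sigma, "sigma", lower = 0)
  n <- max(n, length(A))
  A <- rep_len(A, n)
  if (sigma == 0) return(A)
  sqrt((A + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

#' Analytic mean of the Rician distribution
#'
#' Closed form `sigma*sqrt(pi/2) * L_{1/2}(-A^2/(2*sigma^2))`, evaluated with
#' exponentially scaled Bessel functions so it is stable at arbitrarily high
#' SNR. Used as the reference against which the sampler is validated and for
#' predicting the noise-floor bias of ROI means.
#'
#' @param A true signal amplitude (vectorised).
#' @param sigma noise standard deviation (> 0).
#' @return expected magnitude, same length as `A`.
#' @export
rician_mean <- function(A, sigma) {
  check_scalar(sigma, "sigma", lower = 0)
  if (sigma == 0) return(A)
  t <- A^2 / (4 * sigma^2)
  sigma * sqrt(pi / 2) *
    ((1 + 2 * t) * besselI(t, 0, expon.scaled = TRUE) +
       2 * t * besselI(t, 1, expon.scaled = TRUE))
}

# separable Gaussian smoothing of a 3-D array (replicated edges); used for the
# intratumoural concentration texture
gauss_smooth3 <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-half:half)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1):(half + length(v))]
  }
  d <- dim(arr)
  for (ax in seq_along(d)) {
    if (d[ax] > 1) arr <- apply(arr, setdiff(seq_along(d), ax), conv1)
    # apply() puts the worked axis first; rotate back
    arr <- aperm(array(arr, dim = c(d[ax], d[-ax])),
                 order(c(ax, setdiff(seq_along(d), ax))))
  }
  arr
}

# voxel-centre coordinates (mm) of a grid, 0-based indexing convention:
# voxel [i,j,k] sits at ((i-1)+0.5)*spacing
voxel_coords <- function(grid_shape, voxel_size) {
  lapply(1:3, function(ax) (seq_len(grid_shape[ax]) - 0.5) * voxel_size[ax])
}

# per-voxel Euclidean distance (mm) from a point, as an array on the grid
distance_map <- function(grid_shape, voxel_size, origin) {
  cc <- voxel_coords(grid_shape, voxel_size)
  dx2 <- (cc[[1]] - origin[1])^2
  dy2 <- (cc[[2]] - origin[2])^2
  dz2 <- (cc[[3]] - origin[3])^2
  sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
}

# logical mask of an axis-aligned ellipsoid (semi_axes in mm); a sphere when
# all semi-axes equal
ellipsoid_mask <- function(grid_shape, voxel_size, centre, semi_axes) {
  cc <- voxel_coords(grid_shape, voxel_size)
  u2 <- ((cc[[1]] - centre[1]) / semi_axes[1])^2
  v2 <- ((cc[[2]] - centre[2]) / semi_axes[2])^2
  w2 <- ((cc[[3]] - centre[3]) / semi_axes[3])^2
  outer(outer(u2, v2, `+`), w2, `+`) <= 1
}
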