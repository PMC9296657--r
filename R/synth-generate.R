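# Generators for the synthetic-data module. Each one seeds its own RNG
# stream (withr-free local seed restore) so identical specs give
# bit-identical output and generation order does not leak between calls.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# surface-coil gain field G/(d + d0)^2, unit gain for a volume coil
coil_gain_map <- function(spec) {
  if (spec$coil_mode == "volume")
    return(array(1, dim = spec$grid_shape))
  d <- distance_map(spec$grid_shape, spec$voxel_size, spec$coil_origin)
  # G chosen so the gain averages 1 over the grid; the scale is arbitrary
  # (phantom normalisation cancels it) but unit mean keeps signal units
  # comparable across coil modes
  g <- 1 / (d + spec$coil_d0)^2
  g / mean(g)
}

#' Generate a synthetic sodium image with ROIs and ground truth
#'
#' Builds the concentration map of the scene (background tissue, spherical
#' phantom, ellipsoidal tumour with smoothed Gaussian heterogeneity),
#' multiplies by the coil gain field, and degrades with Rician magnitude
#' noise. The exact body masks and the generating concentration and gain
#' maps are returned so downstream quantification can be tested against
#' ground truth.
#'
#' @param spec a [scene_phantom_spec()].
#' @return list with `image` ([image_volume()]), `rois` ([roi_set()]) and
#'   `truth` (list: `conc_map` mM, `gain_map`, `tumour_mean_conc` -- the
#'   realised in-mask mean of the heterogeneous tumour).
#' @export
#' @examples
#' sc <- generate_sodium_image(scene_phantom_spec(noise_sigma = 0))
#' st <- roi_stats(sc$image, sc$rois)
#' normalize_to_phantom(st)
generate_sodium_image <- function(spec) {
  stopifnot(inherits(spec, "scene_phantom_spec"))
  masks <- scene_masks(spec)
  with_seed(spec$seed, {
    conc <- array(spec$background_conc, dim = spec$grid_shape)
    conc[masks$phantom] <- spec$phantom_conc
    tum <- array(spec$tumour_conc_mean, dim = spec$grid_shape)
    if (spec$tumour_conc_heterogeneity_sd > 0) {
      tex <- array(rnorm(prod(spec$grid_shape)), dim = spec$grid_shape)
      tex <- gauss_smooth3(tex, sigma_vox = 1.5)
      tex <- tex - mean(tex[masks$tumour])
      tex <- tex / max(sd(tex[masks$tumour]), .Machine$double.eps)
      tum <- tum + spec$tumour_conc_heterogeneity_sd * tex
    }
    conc[masks$tumour] <- pmax(tum[masks$tumour], 0)
    gain <- coil_gain_map(spec)
    signal <- conc * gain
    noisy <- array(rrice(length(signal), as.numeric(signal),
                         spec$noise_sigma),
                   dim = spec$grid_shape)
    img <- image_volume(noisy, spec$voxel_size, "na23",
                        meta = list(coil_mode = spec$coil_mode,
                                    seed = spec$seed))
    list(image = img,
         rois = roi_set(masks, img),
         truth = list(conc_map = conc, gain_map = gain,
                      tumour_mean_conc = mean(conc[masks$tumour])))
  })
}

#' Generate a uniform-phantom B1 reference image
#'
#' Images a uniform high-concentration phantom filling the field of view
#' under the same coil as `spec`; this is the reference from which
#' [b1_correct()] fits its \eqn{1/r^2} gain model.
#'
#' @param spec a [scene_phantom_spec()] (geometry and coil are reused).
#' @param conc phantom concentration, mM (default 1000, i.e. 1 M NaCl).
#' @param noise_sigma Rician channel SD for the reference acquisition
#'   (default 0: references are typically high-SNR averages).
#' @return an [image_volume()].
#' @export
generate_b1_reference <- function(spec, conc = 1000, noise_sigma = 0) {
  stopifnot(inherits(spec, "scene_phantom_spec"))
  check_scalar(conc, "conc", lower = .Machine$double.xmin)
  signal <- conc * coil_gain_map(spec)
  with_seed(spec$seed + 1L, {
    noisy <- array(rrice(length(signal), as.numeric(signal), noise_sigma),
                   dim = spec$grid_shape)
    image_volume(noisy, spec$voxel_size, "na23",
                 meta = list(reference = TRUE, conc_mM = conc))
  })
}

#' Generate a synthetic diffusion-weighted series
#'
#' Noise-free signal obeys \eqn{S(b) = S_0 e^{-b \cdot ADC}} voxelwise, with
#' the tumour ellipsoid at `adc_tumour` and everything else at
#' `adc_background`; Rician noise is applied independently per volume.
#'
#' @param spec a [dwi_scene_spec()].
#' @return list with `series` (a [dwi_series()]), `rois` (tumour /
#'   non-tumour masks) and `truth` (list: `adc_map` mm^2/s, `s0_map`).
#' @export
generate_dwi_series <- function(spec) {
  stopifnot(inherits(spec, "dwi_scene_spec"))
  tum <- ellipsoid_mask(spec$grid_shape, spec$voxel_size,
                        spec$tumour_centre, spec$tumour_semi_axes)
  fov <- spec$grid_shape * spec$voxel_size
  ntc <- spec$tumour_centre; ntc[1] <- fov[1] - ntc[1]
  non_tum <- ellipsoid_mask(spec$grid_shape, spec$voxel_size, ntc,
                            spec$tumour_semi_axes)
  adc_map <- array(spec$adc_background, dim = spec$grid_shape)
  adc_map[tum] <- spec$adc_tumour
  s0_map <- array(spec$s0_background, dim = spec$grid_shape)
  s0_map[tum] <- spec$s0_tumour
  with_seed(spec$seed, {
    vols <- lapply(spec$b_values, function(b) {
      s <- s0_map * exp(-b * adc_map)
      noisy <- array(rrice(length(s), as.numeric(s), spec$noise_sigma),
                     dim = spec$grid_shape)
      image_volume(noisy, spec$voxel_size, "dwi",
                   meta = list(b_value = b, seed = spec$seed))
    })
    series <- dwi_series(vols, spec$b_values)
    list(series = series,
         rois = roi_set(list(tumour = tum, non_tumour = non_tum),
                        vols[[1]]),
         truth = list(adc_map = adc_map, s0_map = s0_map))
  })
}

#' Generate a synthetic cohort feature table
#'
#' Draws one row per subject and class from the per-class trivariate
#' Gaussian of `spec`, in the layout expected by the classifier module:
#' columns `subject`, `timepoint`, `region`, `max_na_norm`, `mean_na_norm`,
#' `adc`.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` feature table with `2 * n_per_class` rows.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  feats <- c("max_na_norm", "mean_na_norm", "adc")
  with_seed(spec$seed, {
    rows <- lapply(rownames(spec$class_means), function(cl) {
      sds <- spec$class_sds[cl, ]
      # Sigma = D R D with D = diag(sds): draw z U D + mu, U = chol(R);
      # scaling after the correlated draw keeps sds of exactly 0 legal
      z <- matrix(rnorm(spec$n_per_class * 3), spec$n_per_class, 3)
      x <- sweep(z %*% chol(spec$class_cor), 2, sds, `*`)
      x <- sweep(x, 2, spec$class_means[cl, ], `+`)
      colnames(x) <- feats
      data.frame(subject = sprintf("s%02d", seq_len(spec$n_per_class)),
                 timepoint = spec$timepoint, region = cl, x,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    # ADC is a rate and cannot be negative; the defaults keep this far from
    # the boundary, truncation is a guard for extreme user specs
    tab$adc <- pmax(tab$adc, 0)
    tab
  })
}

#' Generate synthetic SBFI fluorescence traces for one slice
#'
#' Each cell is recorded over a baseline phase (fluorescence at the
#' ground-truth resting intracellular sodium) followed by one
#' ionophore-equilibrated plateau phase per calibration concentration, all
#' on the one-phase-association curve with multiplicative Gaussian frame
#' noise.
#'
#' @param spec an [sbfi_trace_spec()].
#' @return a `data.frame` (`cell`, `phase`, `conc_mM` -- `NA` for baseline,
#'   `frame`, `fluorescence`) with the generating spec attached as attribute
#'   `"spec"`.
#' @export
generate_sbfi_traces <- function(spec) {
  stopifnot(inherits(spec, "sbfi_trace_spec"))
  curve <- function(x) one_phase_value(x, spec$Y0, spec$Plateau, spec$K)
  phases <- data.frame(
    phase = c("baseline", sprintf("cal_%g", spec$calibration_concs)),
    conc_mM = c(NA_real_, spec$calibration_concs),
    level = curve(c(spec$true_resting_nai, spec$calibration_concs)))
  with_seed(spec$seed, {
    grid <- expand.grid(frame = seq_len(spec$frames_per_phase),
                        phase_i = seq_len(nrow(phases)),
                        cell = seq_len(spec$n_cells))
    level <- phases$level[grid$phase_i]
    fl <- level * (1 + spec$noise_cv * rnorm(nrow(grid)))
    out <- data.frame(cell = grid$cell,
                      phase = phases$phase[grid$phase_i],
                      conc_mM = phases$conc_mM[grid$phase_i],
                      frame = grid$frame,
                      fluorescence = fl,
                      stringsAsFactors = FALSE)
    attr(out, "spec") <- spec
    out
  })
}

#' Generate synthetic ion-selective-electrode recordings for one slice
#'
#' Standards are read pre and post experiment directly from the Nernstian
#' response (the post response's sensitivity scaled by `1 + drift_fraction`);
#' tissue recordings at the ground-truth extracellular sodium additionally
#' carry the junction-potential offset. Gaussian voltage noise applies to
#' every reading.
#'
#' @param spec an [isme_recording_spec()].
#' @return list with `standards` (`data.frame`: `conc_mM`, `mV`, `stage`)
#'   and `tissue` (`data.frame`: `recording`, `mV`); the spec is attached as
#'   attribute `"spec"`.
#' @export
generate_isme_recordings <- function(spec) {
  stopifnot(inherits(spec, "isme_recording_spec"))
  nernst <- function(C, slope) slope * log10(C / spec$c_ref)
  with_seed(spec$seed, {
    n_std <- length(spec$standards)
    std <- data.frame(
      conc_mM = rep(spec$standards, 2),
      mV = c(nernst(spec$standards, spec$slope),
             nernst(spec$standards, spec$slope * (1 + spec$drift_fraction))) +
        rnorm(2 * n_std, 0, spec$noise_sd),
      stage = rep(c("pre", "post"), each = n_std),
      stringsAsFactors = FALSE)
    tissue <- data.frame(
      recording = seq_len(spec$n_recordings),
      mV = nernst(spec$true_tissue_nae, spec$slope) + spec$junction_offset +
        rnorm(spec$n_recordings, 0, spec$noise_sd))
    out <- list(standards = std, tissue = tissue)
    attr(out, "spec") <- spec
    out
  })
}
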