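# Scene / cohort / trace specifications for the synthetic-data module.
# Each constructor validates its invariants once, so generators can trust
# their input; defaults encode the study conditions the pipeline targets
# (50 mM phantom, elevated heterogeneous tumour [Na+], reduced tumour ADC,
# 10/20/50 mM SBFI calibration, 48/96/144/192 mM electrode standards).

#' Specification of a synthetic sodium-imaging scene
#'
#' Describes a 3-D magnitude \eqn{^{23}}Na scene: a spherical NaCl reference
#' phantom, an ellipsoidal tumour with heterogeneous elevated concentration,
#' a contralateral non-tumour region at baseline, an optional surface-coil
#' \eqn{1/r^2} gain field and Rician magnitude noise.
#'
#' Default concentrations follow the tissue values the pipeline is designed
#' around: 50 mM phantom, 46.9 mM mean tumour, 29.7 mM background tissue.
#'
#' @param grid_shape integer length-3 voxel grid.
#' @param voxel_size mm per voxel along each axis.
#' @param phantom_centre,phantom_radius sphere (mm) modelling the NaCl tube.
#' @param phantom_conc phantom concentration, mM.
#' @param tumour_centre,tumour_semi_axes tumour ellipsoid (mm).
#' @param tumour_conc_mean mean tumour concentration, mM.
#' @param tumour_conc_heterogeneity_sd SD (mM) of the smoothed Gaussian
#'   concentration texture inside the tumour; 0 gives a uniform tumour.
#' @param background_conc concentration of all non-phantom, non-tumour
#'   tissue, mM; also the non-tumour ROI value.
#' @param non_tumour_centre centre of the contralateral non-tumour ROI; by
#'   default the tumour centre mirrored in x about the grid midline.
#' @param coil_mode `"volume"` (flat gain) or `"surface"` (\eqn{1/r^2}).
#' @param coil_origin coil position (mm) for surface mode.
#' @param coil_d0 gain-floor distance (mm) avoiding the \eqn{1/r^2}
#'   singularity at the coil plane.
#' @param noise_sigma Rician channel SD, in the same arbitrary units as the
#'   concentration-proportional signal.
#' @param seed integer seed; identical specs and seeds give bit-identical
#'   scenes.
#' @return a validated `scene_phantom_spec`.
#' @export
scene_phantom_spec <- function(grid_shape = c(48L, 48L, 12L),
                               voxel_size = c(0.5, 0.5, 1.0),
                               phantom_centre = c(12, 4.5, 6),
                               phantom_radius = 2.5,
                               phantom_conc = 50,
                               tumour_centre = c(7, 16, 6),
                               tumour_semi_axes = c(3.5, 3, 3),
                               tumour_conc_mean = 46.9,
                               tumour_conc_heterogeneity_sd = 5,
                               background_conc = 29.7,
                               non_tumour_centre = NULL,
                               coil_mode = c("volume", "surface"),
                               coil_origin = c(12, 0, 6),
                               coil_d0 = 5,
                               noise_sigma = 1.5,
                               seed = 1L) {
  coil_mode <- match.arg(coil_mode)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop_config("grid_shape must be three positive integers")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_config("voxel_size must be three positive values")
  for (v in c("phantom_conc", "tumour_conc_mean", "background_conc",
              "tumour_conc_heterogeneity_sd"))
    check_scalar(get(v), v, lower = 0)
  check_scalar(phantom_radius, "phantom_radius", lower = .Machine$double.eps)
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  check_scalar(coil_d0, "coil_d0", lower = .Machine$double.eps)
  fov <- grid_shape * voxel_size
  inside <- function(centre, extent)
    all(centre - extent >= 0) && all(centre + extent <= fov)
  if (!inside(phantom_centre, rep(phantom_radius, 3)))
    stop_config("phantom extends outside the grid")
  if (!inside(tumour_centre, tumour_semi_axes))
    stop_config("tumour extends outside the grid")
  if (is.null(non_tumour_centre)) {
    non_tumour_centre <- tumour_centre
    non_tumour_centre[1] <- fov[1] - tumour_centre[1]
  }
  if (!inside(non_tumour_centre, tumour_semi_axes))
    stop_config("non-tumour region extends outside the grid")
  # body separation guaranteed at construction, re-checked on generation
  spec <- structure(list(
    grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
    phantom_centre = as.numeric(phantom_centre),
    phantom_radius = phantom_radius, phantom_conc = phantom_conc,
    tumour_centre = as.numeric(tumour_centre),
    tumour_semi_axes = as.numeric(tumour_semi_axes),
    tumour_conc_mean = tumour_conc_mean,
    tumour_conc_heterogeneity_sd = tumour_conc_heterogeneity_sd,
    background_conc = background_conc,
    non_tumour_centre = as.numeric(non_tumour_centre),
    coil_mode = coil_mode, coil_origin = as.numeric(coil_origin),
    coil_d0 = coil_d0, noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "scene_phantom_spec")
  m <- scene_masks(spec)
  if (any(m$phantom & m$tumour) || any(m$phantom & m$non_tumour) ||
      any(m$tumour & m$non_tumour))
    stop_config("phantom, tumour and non-tumour bodies overlap")
  spec
}

# masks for the three scene bodies
scene_masks <- function(spec) {
  list(
    tumour = ellipsoid_mask(spec$grid_shape, spec$voxel_size,
                            spec$tumour_centre, spec$tumour_semi_axes),
    non_tumour = ellipsoid_mask(spec$grid_shape, spec$voxel_size,
                                spec$non_tumour_centre, spec$tumour_semi_axes),
    phantom = ellipsoid_mask(spec$grid_shape, spec$voxel_size,
                             spec$phantom_centre, rep(spec$phantom_radius, 3))
  )
}

#' Specification of a synthetic diffusion-weighted series
#'
#' Mono-exponential decay \eqn{S(b) = S_0 e^{-b \cdot ADC}} over a tumour
#' ellipsoid (low ADC) embedded in background tissue (higher ADC), with
#' independent Rician noise per volume.
#'
#' @param b_values s/mm^2; must be distinct, non-negative and include 0.
#' @param grid_shape,voxel_size,tumour_centre,tumour_semi_axes scene geometry
#'   as in [scene_phantom_spec()].
#' @param adc_tumour,adc_background generating ADCs, mm^2/s (> 0).
#' @param s0_tumour,s0_background b = 0 signal levels (arbitrary units).
#' @param noise_sigma Rician channel SD.
#' @param seed integer seed.
#' @return a validated `dwi_scene_spec`.
#' @export
dwi_scene_spec <- function(b_values = c(0, 100, 300, 700),
                           grid_shape = c(32L, 32L, 8L),
                           voxel_size = c(0.5, 0.5, 1.0),
                           tumour_centre = c(5, 8, 4),
                           tumour_semi_axes = c(3, 2.5, 2.5),
                           adc_tumour = 0.7e-3,
                           adc_background = 1.6e-3,
                           s0_tumour = 1000,
                           s0_background = 800,
                           noise_sigma = 0,
                           seed = 1L) {
  b_values <- as.numeric(b_values)
  if (anyDuplicated(b_values) || any(b_values < 0))
    stop_config("b_values must be distinct and non-negative")
  if (!any(b_values == 0))
    stop_config("b_values must include b = 0 (the S0 volume)")
  check_scalar(adc_tumour, "adc_tumour", lower = 0)
  check_scalar(adc_background, "adc_background", lower = 0)
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  structure(list(b_values = b_values, grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 tumour_centre = as.numeric(tumour_centre),
                 tumour_semi_axes = as.numeric(tumour_semi_axes),
                 adc_tumour = adc_tumour, adc_background = adc_background,
                 s0_tumour = s0_tumour, s0_background = s0_background,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "dwi_scene_spec")
}

#' Specification of a synthetic imaging cohort feature table
#'
#' Per-class trivariate Gaussian over (max \eqn{^{23}}Na, mean \eqn{^{23}}Na,
#' ADC). Defaults emulate the observed structure: tumours show elevated,
#' phantom-normalised sodium signal and reduced ADC, so the pooled Na-ADC
#' correlation is negative.
#'
#' @param n_per_class subjects per class; each subject contributes one row.
#' @param class_means 2 x 3 matrix (rows `tumour`, `non_tumour`; columns
#'   `max_na_norm`, `mean_na_norm`, `adc` in mm^2/s).
#' @param class_sds 2 x 3 matrix of per-feature SDs.
#' @param class_cor within-class 3 x 3 correlation matrix (shared by both
#'   classes); must be positive-definite.
#' @param timepoint label carried into the table (the real cohorts pooled
#'   weeks 2-4).
#' @param seed integer seed.
#' @return a validated `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 15L,
                        class_means = rbind(
                          tumour = c(max_na_norm = 2.0, mean_na_norm = 1.10,
                                     adc = 0.70e-3),
                          non_tumour = c(max_na_norm = 0.90,
                                         mean_na_norm = 0.65, adc = 1.55e-3)),
                        class_sds = rbind(
                          tumour = c(0.35, 0.18, 0.12e-3),
                          non_tumour = c(0.15, 0.10, 0.18e-3)),
                        class_cor = matrix(c(1, 0.7, -0.4,
                                             0.7, 1, -0.35,
                                             -0.4, -0.35, 1), 3, 3),
                        timepoint = "pooled",
                        seed = 1L) {
  if (n_per_class < 1L) stop_config("n_per_class must be at least 1")
  if (!all(rownames(class_means) == c("tumour", "non_tumour")))
    stop_config("class_means rows must be tumour, non_tumour")
  if (!isSymmetric(unname(class_cor)))
    stop_config("class_cor must be symmetric")
  ev <- eigen(class_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12)
    stop_config("class_cor (hence the covariance) must be positive-definite")
  if (any(class_sds < 0)) stop_config("class_sds must be non-negative")
  structure(list(n_per_class = as.integer(n_per_class),
                 class_means = class_means, class_sds = class_sds,
                 class_cor = class_cor, timepoint = timepoint,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Specification of synthetic SBFI fluorescence traces
#'
#' One tumour slice: `n_cells` cells, each recorded over a resting baseline
#' phase followed by one plateau phase per calibration concentration (the
#' ionophore-equilibrated steps). Plateau fluorescence follows the
#' one-phase-association curve `Y0 + (Plateau - Y0) * (1 - exp(-K * x))`
#' with multiplicative Gaussian frame noise.
#'
#' @param n_cells cells in the slice (the study design used 11-16).
#' @param true_resting_nai ground-truth resting intracellular sodium, mM.
#' @param calibration_concs strictly increasing calibration steps, mM.
#' @param frames_per_phase acquisition frames per perfusion phase (>= 3:
#'   downstream averaging uses the final three frames).
#' @param Y0,Plateau,K one-phase-association curve parameters (`K` in 1/mM,
#'   `K > 0`, `Plateau > Y0`).
#' @param noise_cv multiplicative frame-noise coefficient of variation.
#' @param seed integer seed.
#' @return a validated `sbfi_trace_spec`.
#' @export
sbfi_trace_spec <- function(n_cells = 13L,
                            true_resting_nai = 25.9,
                            calibration_concs = c(10, 20, 50),
                            frames_per_phase = 10L,
                            Y0 = 1, Plateau = 2, K = 0.05,
                            noise_cv = 0.02,
                            seed = 1L) {
  if (frames_per_phase < 3L)
    stop_config("frames_per_phase must be >= 3 (final-three-frame averaging)")
  if (is.unsorted(calibration_concs, strictly = TRUE))
    stop_config("calibration_concs must be strictly increasing")
  if (length(calibration_concs) < 3L)
    stop_config("at least 3 calibration concentrations are required")
  check_scalar(K, "K", lower = .Machine$double.xmin)
  if (Plateau <= Y0) stop_config("Plateau must exceed Y0")
  check_scalar(true_resting_nai, "true_resting_nai", lower = 0)
  check_scalar(noise_cv, "noise_cv", lower = 0)
  structure(list(n_cells = as.integer(n_cells),
                 true_resting_nai = true_resting_nai,
                 calibration_concs = as.numeric(calibration_concs),
                 frames_per_phase = as.integer(frames_per_phase),
                 Y0 = Y0, Plateau = Plateau, K = K, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "sbfi_trace_spec")
}

#' Specification of synthetic ion-selective-electrode recordings
#'
#' One tumour slice: a near-Nernstian electrode
#' `V = slope * log10(C / c_ref)` is sampled at the calibration standards
#' (pre and post experiment, the post response scaled by a sensitivity drift)
#' and at the tissue, where the recorded voltage additionally carries the
#' bath-vs-tube junction-potential offset.
#'
#' @param standards strictly increasing calibration concentrations, mM
#'   (>= 3; the rational Pade(1,1) calibration needs three points).
#' @param slope electrode sensitivity, mV/decade (58 is near-Nernstian at
#'   room temperature).
#' @param c_ref reference concentration (mM) anchoring the response curve.
#' @param junction_offset bath-minus-tube junction potential, mV, added to
#'   tissue recordings only.
#' @param true_tissue_nae ground-truth tissue extracellular sodium, mM.
#' @param n_recordings tissue recordings per slice (study design: 12).
#' @param noise_sd Gaussian voltage noise SD, mV, on every recording.
#' @param drift_fraction relative change of the post-experiment sensitivity;
#'   the QC bound in routine use is 5%.
#' @param seed integer seed.
#' @return a validated `isme_recording_spec`.
#' @export
isme_recording_spec <- function(standards = c(48, 96, 144, 192),
                                slope = 58,
                                c_ref = 144,
                                junction_offset = 10,
                                true_tissue_nae = 157.8,
                                n_recordings = 12L,
                                noise_sd = 0.3,
                                drift_fraction = 0,
                                seed = 1L) {
  if (length(standards) < 3L)
    stop_config("at least 3 standards are required for a Pade(1,1) fit")
  if (is.unsorted(standards, strictly = TRUE) || any(standards <= 0))
    stop_config("standards must be positive and strictly increasing")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(drift_fraction, "drift_fraction", lower = 0, upper = 0.05)
  check_scalar(true_tissue_nae, "true_tissue_nae",
               lower = .Machine$double.xmin)
  structure(list(standards = as.numeric(standards), slope = slope,
                 c_ref = c_ref, junction_offset = junction_offset,
                 true_tissue_nae = true_tissue_nae,
                 n_recordings = as.integer(n_recordings),
                 noise_sd = noise_sd, drift_fraction = drift_fraction,
                 seed = as.integer(seed)),
            class = "isme_recording_spec")
}
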