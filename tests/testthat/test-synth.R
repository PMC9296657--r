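# synthetic-data generators: determinism, noise models, ground-truth
# fidelity, configuration guards

test_that("all generators are bit-identical under identical spec and seed", {
  twice <- function(f, spec) list(f(spec), f(spec))
  p <- twice(generate_sodium_image, scene_phantom_spec(seed = 11L))
  expect_identical(p[[1]], p[[2]])
  d <- twice(generate_dwi_series, dwi_scene_spec(noise_sigma = 5, seed = 11L))
  expect_identical(d[[1]], d[[2]])
  co <- twice(generate_cohort, cohort_spec(seed = 11L))
  expect_identical(co[[1]], co[[2]])
  tr <- twice(generate_sbfi_traces, sbfi_trace_spec(seed = 11L))
  expect_identical(tr[[1]], tr[[2]])
  re <- twice(generate_isme_recordings, isme_recording_spec(seed = 11L))
  expect_identical(re[[1]], re[[2]])
  # different seeds give different noise realisations
  expect_false(identical(
    generate_sodium_image(scene_phantom_spec(seed = 1L))$image$data,
    generate_sodium_image(scene_phantom_spec(seed = 2L))$image$data))
})

test_that("noise-free volume-coil image equals the concentration map", {
  sc <- generate_sodium_image(scene_phantom_spec(noise_sigma = 0))
  expect_identical(sc$image$data, sc$truth$conc_map)
  # masks carve out exactly the generating bodies
  expect_true(all(sc$image$data[sc$rois$masks$phantom] == 50))
  expect_true(all(sc$image$data[sc$rois$masks$non_tumour] == 29.7))
})

test_that("surface-coil voxel ratios follow the 1/(d + d0)^2 gain law", {
  sp <- quiet_scene_spec(coil_mode = "surface")
  sc <- generate_sodium_image(sp)
  d <- natremri:::distance_map(sp$grid_shape, sp$voxel_size, sp$coil_origin)
  i1 <- which(sc$rois$masks$tumour)[1]
  i2 <- which(sc$rois$masks$phantom)[1]
  expected <- (sc$truth$conc_map[i1] / sc$truth$conc_map[i2]) *
    (d[i2] + sp$coil_d0)^2 / (d[i1] + sp$coil_d0)^2
  expect_equal(sc$image$data[i1] / sc$image$data[i2], expected,
               tolerance = 1e-12)
})

test_that("Rician sampler matches the analytic and integral means", {
  # analytic closed form against numeric integration of the density
  for (snr in c(0, 0.5, 1, 3, 10, 50))
    expect_equal(rician_mean(snr * 2, 2), oracle_rician_mean(snr * 2, 2),
                 tolerance = 1e-8)
  # simulated mean over 1e5 draws within 0.5% of the analytic mean
  set.seed(42)
  for (A in c(0.5, 2, 10)) {
    m <- mean(rrice(1e5, A, 1))
    expect_equal(m, rician_mean(A, 1), tolerance = 5e-3)
  }
})

test_that("high-SNR ROI means sit within 2% of the noise-free value", {
  sp <- scene_phantom_spec(noise_sigma = 46.9 / 25,
                           tumour_conc_heterogeneity_sd = 0, seed = 5L)
  sc <- generate_sodium_image(sp)
  roi_mean <- mean(sc$image$data[sc$rois$masks$tumour])
  expect_gt(sum(sc$rois$masks$tumour), 500)
  expect_equal(roi_mean, 46.9, tolerance = 0.02)
})

test_that("scene configuration errors are caught", {
  expect_error(scene_phantom_spec(grid_shape = c(0, 10, 10)), "positive")
  expect_error(scene_phantom_spec(phantom_centre = c(7, 16, 6)), "overlap")
  expect_error(scene_phantom_spec(tumour_centre = c(1, 1, 1)),
               "outside the grid")
  expect_error(scene_phantom_spec(background_conc = -1), "must be in")
})

test_that("DWI signal obeys S0 exp(-b ADC) with exact ground truth", {
  # ADC = 0 everywhere: all volumes identical before noise
  sp0 <- dwi_scene_spec(adc_tumour = 0, adc_background = 0, noise_sigma = 0)
  d0 <- generate_dwi_series(sp0)
  for (v in d0$series$volumes[-1])
    expect_identical(v$data, d0$series$volumes[[1]]$data)
  # closed-form value at b = 700 for ADC 1e-3, S0 1000
  sp <- dwi_scene_spec(adc_tumour = 1e-3, adc_background = 1e-3,
                       s0_tumour = 1000, s0_background = 1000,
                       noise_sigma = 0)
  d <- generate_dwi_series(sp)
  b700 <- which(d$series$b_values == 700)
  expect_equal(d$series$volumes[[b700]]$data[1], 496.585, tolerance = 1e-6)
  expect_error(dwi_scene_spec(b_values = c(100, 300)), "b = 0")
  expect_error(dwi_scene_spec(b_values = c(0, 100, 100)), "distinct")
})

test_that("cohort generator hits its class parameters", {
  # zero covariance, distinct means: every point at its class mean
  sp <- cohort_spec(n_per_class = 5L,
                    class_sds = rbind(tumour = c(0, 0, 0),
                                      non_tumour = c(0, 0, 0)))
  tab <- generate_cohort(sp)
  for (cl in c("tumour", "non_tumour"))
    expect_equal(unname(as.matrix(
      tab[tab$region == cl, c("max_na_norm", "mean_na_norm", "adc")])),
      matrix(sp$class_means[cl, ], 5, 3, byrow = TRUE), tolerance = 1e-12)
  # large-n empirical means within 3 SE of spec means
  big <- generate_cohort(cohort_spec(n_per_class = 10000L, seed = 8L))
  spd <- cohort_spec()
  for (cl in c("tumour", "non_tumour")) {
    x <- as.matrix(big[big$region == cl,
                       c("max_na_norm", "mean_na_norm", "adc")])
    se <- spd$class_sds[cl, ] / sqrt(10000)
    expect_true(all(abs(colMeans(x) - spd$class_means[cl, ]) <= 3 * se))
  }
  # pooled sodium-ADC correlation is negative under defaults
  tab2 <- generate_cohort(cohort_spec(seed = 3L))
  expect_lt(pearson_cor(tab2$max_na_norm, tab2$adc)$r, 0)
  expect_error(cohort_spec(class_cor = matrix(c(1, 2, 2, 1), 2, 2)),
               "positive-definite|symmetric|rows")
})

test_that("SBFI traces follow the one-phase-association curve", {
  sp <- sbfi_trace_spec(noise_cv = 0, n_cells = 2L)
  tr <- generate_sbfi_traces(sp)
  pl <- sbfi_plateau_table(tr)
  cal_rows <- pl[!is.na(pl$conc_mM) & pl$cell == 1, ]
  expect_equal(cal_rows$fluorescence,
               one_phase_value(cal_rows$conc_mM, 1, 2, 0.05),
               tolerance = 1e-12)
  # baseline fluorescence at the resting sodium: 1 + (1 - exp(-0.05*25.9))
  base <- pl$fluorescence[is.na(pl$conc_mM) & pl$cell == 1]
  expect_equal(base, 1.7261, tolerance = 1e-4)
  expect_error(sbfi_trace_spec(frames_per_phase = 2), ">= 3")
  expect_error(sbfi_trace_spec(calibration_concs = c(20, 10, 50)),
               "increasing")
  expect_error(sbfi_trace_spec(Y0 = 2, Plateau = 1), "exceed")
})

test_that("electrode recordings are Nernstian with offset and drift", {
  sp <- isme_recording_spec(noise_sd = 0, drift_fraction = 0)
  re <- generate_isme_recordings(sp)
  pre <- re$standards[re$standards$stage == "pre", ]
  expect_equal(pre$mV, 58 * log10(pre$conc_mM / 144), tolerance = 1e-12)
  # tissue voltage carries the junction offset
  expect_equal(re$tissue$mV,
               rep(58 * log10(157.8 / 144) + 10, 12), tolerance = 1e-12)
  # doubling concentration raises V by slope * log10(2) = 17.46 mV
  sp2 <- isme_recording_spec(standards = c(48, 144, 288), noise_sd = 0)
  re2 <- generate_isme_recordings(sp2)
  pre2 <- re2$standards[re2$standards$stage == "pre", ]
  expect_equal(pre2$mV[pre2$conc_mM == 288] - pre2$mV[pre2$conc_mM == 144],
               58 * log10(2), tolerance = 1e-10)
  expect_equal(58 * log10(2), 17.46, tolerance = 1e-3)
  # five percent drift scales the post sensitivity by exactly 1.05
  spd <- isme_recording_spec(noise_sd = 0, drift_fraction = 0.05)
  red <- generate_isme_recordings(spd)
  post <- red$standards[red$standards$stage == "post", ]
  pred <- red$standards[red$standards$stage == "pre", ]
  expect_equal(post$mV, 1.05 * pred$mV, tolerance = 1e-12)
  expect_error(isme_recording_spec(standards = c(48, 96)), "3 standards")
  expect_error(isme_recording_spec(drift_fraction = 0.2), "must be in")
})
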