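# ion calibrations: one-phase-association (SBFI) and Pade(1,1) (electrode)
# fitting, closed-form inversions, drift QC, study-level recovery

test_that("one-phase fit interpolates exact three-point data", {
  conc <- c(10, 20, 50)
  cal <- fit_one_phase(conc, one_phase_value(conc, 1, 2, 0.05))
  expect_equal(cal$Y0, 1, tolerance = 1e-6)
  expect_equal(cal$Plateau, 2, tolerance = 1e-6)
  expect_equal(cal$K, 0.05, tolerance = 1e-6)
  expect_lt(cal$residual, 1e-12)
  expect_error(fit_one_phase(c(10, 20), c(1, 2)), "3 distinct")
  expect_warning(fit_one_phase(conc, c(2, 1.5, 1.2)), "not increasing")
})

test_that("noisy fits keep the curve accurate even where K is uncertain", {
  # with 3 plateau points and 3 parameters the interpolant absorbs the
  # noise, so K itself is ill-conditioned (about 13% spread per 1% of
  # plateau noise) while the fitted curve, and hence any interpolated
  # concentration, stays accurate; both halves are pinned down here
  conc <- c(10, 20, 50)
  truth <- one_phase_value(conc, 1, 2, 0.05)
  set.seed(14)
  out <- replicate(100, {
    cal <- fit_one_phase(conc, truth * (1 + 0.02 * rnorm(3)))
    base <- one_phase_value(25.9, 1, 2, 0.05)
    c(k_err = abs(cal$K - 0.05) / 0.05,
      nai_err = abs(interpolate_nai(cal, base)$nai_mM - 25.9))
  })
  expect_lt(median(out["k_err", ]), 0.30)
  # single-fit inversion error is ~2 mM at this noise (curve slope near
  # 26 mM maps a 2% plateau error to ~2.5 mM); the study pipeline then
  # averages 3 frames x ~40 cells to reach sub-mM precision
  expect_lt(median(out["nai_err", ]), 2.5)
})

test_that("baseline inversion is the closed-form curve inverse", {
  conc <- c(10, 20, 50)
  cal <- fit_one_phase(conc, one_phase_value(conc, 1, 2, 0.05))
  expect_equal(interpolate_nai(cal, 1.7261)$nai_mM, 25.9, tolerance = 1e-3)
  # a baseline equal to a calibration knot returns the knot concentration
  expect_equal(interpolate_nai(cal, one_phase_value(20, 1, 2, 0.05))$nai_mM,
               20, tolerance = 1e-6)
  z <- interpolate_nai(cal, cal$Y0 - 0.01)
  expect_equal(z$nai_mM, 0)
  expect_true(z$clipped)
  expect_error(interpolate_nai(cal, cal$Plateau + 0.1), "plateau")
  # round trip over the calibrated range to 1e-9
  for (x in c(1, 7.3, 25.9, 60, 120))
    expect_equal(
      interpolate_nai(cal, one_phase_value(x, cal$Y0, cal$Plateau,
                                           cal$K))$nai_mM,
      x, tolerance = 1e-9)
})

test_that("Pade(1,1) fitting is exact in class and degenerates to a line", {
  conc <- c(48, 96, 144, 192)
  v <- (3 + 0.4 * conc) / (1 + 0.002 * conc)
  cal <- fit_pade11(conc, v)
  expect_equal(cal$a, 3, tolerance = 1e-6)
  expect_equal(cal$b, 0.4, tolerance = 1e-6)
  expect_equal(cal$c, 0.002, tolerance = 1e-6)
  expect_lt(cal$residual, 1e-12)
  # three points: exact rational interpolation
  cal3 <- fit_pade11(conc[1:3], v[1:3])
  expect_equal(pade_value <- (cal3$a + cal3$b * conc[1:3]) /
                 (1 + cal3$c * conc[1:3]), v[1:3], tolerance = 1e-9)
  # linear data: c ~ 0 and (a, b) match ordinary least squares
  vl <- -5 + 0.25 * conc
  call <- fit_pade11(conc, vl)
  expect_equal(call$c, 0, tolerance = 1e-6)
  lf <- lm(vl ~ conc)
  expect_equal(call$a, unname(coef(lf)[1]), tolerance = 1e-4)
  expect_equal(call$b, unname(coef(lf)[2]), tolerance = 1e-6)
  expect_error(fit_pade11(c(48, 96), c(1, 2)), "3 distinct")
})

test_that("Nernstian standards are fitted within 0.5 mV everywhere", {
  conc <- c(48, 96, 144, 192)
  v <- 58 * log10(conc / 144)
  cal <- fit_pade11(conc, v)
  fitted <- (cal$a + cal$b * conc) / (1 + cal$c * conc)
  expect_lt(max(abs(fitted - v)), 0.5)
})

test_that("voltage inversion honours offsets and refuses extrapolation", {
  conc <- c(48, 96, 144, 192)
  v <- 58 * log10(conc / 144)
  cal <- fit_pade11(conc, v)
  # a voltage on the fitted curve returns that concentration
  vf <- (cal$a + cal$b * 96) / (1 + cal$c * 96)
  expect_equal(interpolate_nae(cal, vf), 96, tolerance = 1e-9)
  # adding k mV to both the recording and the offset changes nothing
  expect_equal(interpolate_nae(cal, vf + 12.5, junction_offset = 12.5),
               interpolate_nae(cal, vf), tolerance = 1e-12)
  expect_error(interpolate_nae(cal, 100), "extrapolate")
  # round trip across the standard range to 1e-9
  for (x in c(50, 100, 157.8, 190)) {
    vx <- (cal$a + cal$b * x) / (1 + cal$c * x)
    expect_equal(interpolate_nae(cal, vx), x, tolerance = 1e-9)
  }
})

test_that("drift check flags sensitivity changes beyond 5%", {
  conc <- c(48, 96, 144, 192)
  v <- 58 * log10(conc / 144)
  cal <- fit_pade11(conc, v)
  same <- drift_check(cal, cal)
  expect_equal(same$drift, 0)
  expect_true(same$pass)
  at5 <- drift_check(cal, fit_pade11(conc, 1.05 * v))
  expect_equal(at5$drift, 0.05, tolerance = 1e-9)
  expect_true(at5$pass)
  expect_false(drift_check(cal, fit_pade11(conc, 1.10 * v))$pass)
})

test_that("study-level SBFI recovery is unbiased at the design size", {
  set.seed(15)
  traces <- lapply(1:3, function(i)
    generate_sbfi_traces(sbfi_trace_spec(n_cells = sample(11:16, 1),
                                         seed = 100L + i)))
  est <- estimate_nai_study(traces)
  expect_equal(length(est$slice_means), 3)
  expect_lt(abs(est$grand_mean - 25.9), 1.5)
  # pooled-fit mode stays close to the per-cell default
  est_p <- estimate_nai_study(traces, pooled = TRUE)
  expect_lt(abs(est_p$grand_mean - est$grand_mean), 1.5)
})

test_that("study-level electrode recovery lands within 2 mM of truth", {
  recs <- lapply(1:6, function(i)
    generate_isme_recordings(isme_recording_spec(seed = 200L + i)))
  est <- estimate_nae_study(recs, junction_offset = 10)
  expect_equal(length(est$slice_means), 6)
  expect_lt(abs(est$grand_mean - 157.8), 2)
  expect_true(all(is.na(est$drift_pass) | est$drift_pass))
  # drifted electrodes are flagged by the per-slice QC
  drifted <- generate_isme_recordings(
    isme_recording_spec(drift_fraction = 0.05, noise_sd = 0, seed = 1L))
  est_d <- estimate_nae_study(list(drifted), junction_offset = 10)
  expect_equal(est_d$drift[1], 0.05, tolerance = 1e-6)
})
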