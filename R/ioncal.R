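# Ex vivo ion calibrations.
# SBFI fluorescence -> intracellular sodium via a one-phase-association
# curve; electrode voltage -> extracellular sodium via a Pade(1,1)
# calibration with junction-offset subtraction and sensitivity-drift QC.
#
# Both fits use variable projection: the model is linear in all parameters
# but one (the rate K, or the denominator coefficient c), so that parameter
# is found by a deterministic 1-D search with the rest solved exactly by
# linear least squares at each candidate. This is seedless, has no
# starting-value failure modes, and handles the exact-fit (zero-residual)
# three-point case that defeats generic nonlinear optimisers.

#' One-phase-association curve value
#'
#' `Y0 + (Plateau - Y0) * (1 - exp(-K * x))`.
#'
#' @param x concentration, mM.
#' @param Y0 response at zero concentration.
#' @param Plateau saturating response.
#' @param K rate constant, 1/mM.
#' @return curve value(s).
#' @export
one_phase_value <- function(x, Y0, Plateau, K) {
  Y0 + (Plateau - Y0) * (1 - exp(-K * x))
}

#' Fit a one-phase-association calibration to SBFI plateaus
#'
#' Least-squares fit of `Y(x) = Y0 + (Plateau - Y0)(1 - exp(-K x))` to the
#' per-concentration plateau fluorescences of one cell. K is profiled over
#' a log-spaced grid refined by golden-section search; (Y0, Plateau) are
#' solved linearly at each K. With three distinct concentrations and three
#' parameters the fit interpolates exactly (residual 0).
#'
#' @param conc calibration concentrations, mM (>= 3 distinct values).
#' @param fluorescence plateau fluorescence at each concentration.
#' @param k_range search interval for K, 1/mM.
#' @return object of class `sbfi_calibration`: `Y0`, `Plateau`, `K`,
#'   `residual` (RSS), `conc`, `fluorescence`.
#' @export
#' @examples
#' f <- one_phase_value(c(10, 20, 50), 1, 2, 0.05)
#' fit_one_phase(c(10, 20, 50), f)
fit_one_phase <- function(conc, fluorescence, k_range = c(1e-4, 1)) {
  conc <- as.numeric(conc); y <- as.numeric(fluorescence)
  if (length(conc) < 3L || length(unique(conc)) < 3L)
    stop_config("at least 3 distinct calibration concentrations required")
  if (length(conc) != length(y)) stop_config("conc/fluorescence mismatch")
  if (any(conc < 0)) stop_config("concentrations must be non-negative")
  # monotonicity judged on per-concentration means so pooled replicate
  # points do not trip the check through within-level noise
  conc_means <- tapply(y, conc, mean)
  monotone_warn <- is.unsorted(as.numeric(conc_means))
  rss_k <- function(K) {
    X <- cbind(1, 1 - exp(-K * conc))
    sum(lm.fit(X, y)$residuals^2)
  }
  ks <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = 40))
  rss <- vapply(ks, rss_k, numeric(1))
  i <- which.min(rss)
  lo <- ks[max(1L, i - 1L)]; hi <- ks[min(length(ks), i + 1L)]
  opt <- optimize(rss_k, c(lo, hi), tol = 1e-12)
  K <- opt$minimum
  ab <- lm.fit(cbind(1, 1 - exp(-K * conc)), y)$coefficients
  Y0 <- unname(ab[1]); Plateau <- unname(ab[1] + ab[2])
  cal <- structure(list(Y0 = Y0, Plateau = Plateau, K = K,
                        residual = opt$objective, conc = conc,
                        fluorescence = y),
                   class = "sbfi_calibration")
  if (monotone_warn || Plateau <= Y0) {
    warning("plateau fluorescence is not increasing with concentration; ",
            "calibration is unreliable")
    cal$failed <- TRUE
  }
  cal
}

#' @export
print.sbfi_calibration <- function(x, ...) {
  cat(sprintf(
    "<sbfi_calibration> Y0 %.4g Plateau %.4g K %.4g /mM (RSS %.3g)\n",
    x$Y0, x$Plateau, x$K, x$residual))
  invisible(x)
}

#' Invert a baseline fluorescence to intracellular sodium
#'
#' Closed-form inversion of the fitted one-phase-association curve:
#' `x = -ln(1 - (F - Y0)/(Plateau - Y0)) / K`. A baseline at or below Y0
#' returns 0 mM with `clipped = TRUE`; a baseline at or above the plateau
#' is outside the curve's range and errors.
#'
#' @param cal an [fit_one_phase()] calibration.
#' @param baseline_fluorescence resting-phase fluorescence F.
#' @return list: `nai_mM`, `clipped`.
#' @export
#' @examples
#' cal <- fit_one_phase(c(10, 20, 50), one_phase_value(c(10, 20, 50), 1, 2, 0.05))
#' interpolate_nai(cal, 1.7261)$nai_mM # ~25.9
interpolate_nai <- function(cal, baseline_fluorescence) {
  stopifnot(inherits(cal, "sbfi_calibration"))
  f <- baseline_fluorescence
  check_scalar(f, "baseline_fluorescence")
  if (f >= cal$Plateau)
    stop_config("baseline fluorescence at or above the plateau; ",
                "concentration is outside the calibrated range")
  if (f <= cal$Y0) return(list(nai_mM = 0, clipped = TRUE))
  frac <- (f - cal$Y0) / (cal$Plateau - cal$Y0)
  list(nai_mM = -log(1 - frac) / cal$K, clipped = FALSE)
}

#' Average the final frames of each perfusion phase
#'
#' Reduces a trace table (as from [generate_sbfi_traces()] or a CSV with
#' the same columns) to one plateau value per cell and phase: the mean of
#' the final `n_frames` acquisition frames.
#'
#' @param traces `data.frame` with `cell`, `phase`, `conc_mM`, `frame`,
#'   `fluorescence`.
#' @param n_frames frames to average from the end of each phase (default 3).
#' @return `data.frame` with one row per (cell, phase): `cell`, `phase`,
#'   `conc_mM`, `fluorescence`.
#' @export
sbfi_plateau_table <- function(traces, n_frames = 3L) {
  need <- c("cell", "phase", "conc_mM", "frame", "fluorescence")
  miss <- setdiff(need, names(traces))
  if (length(miss))
    stop_config("traces lack columns: ", paste(miss, collapse = ", "))
  if (min(tapply(traces$frame, interaction(traces$cell, traces$phase,
                                           drop = TRUE), length)) < n_frames)
    stop_config("fewer than ", n_frames, " frames in some phase")
  traces <- traces[order(traces$cell, traces$phase, traces$frame), ]
  agg <- lapply(split(traces, list(traces$cell, traces$phase), drop = TRUE),
                function(d) {
                  d <- tail(d[order(d$frame), ], n_frames)
                  data.frame(cell = d$cell[1], phase = d$phase[1],
                             conc_mM = d$conc_mM[1],
                             fluorescence = mean(d$fluorescence),
                             stringsAsFactors = FALSE)
                })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$cell, out$conc_mM, na.last = FALSE), ]
}

#' Estimate resting intracellular sodium for a study of slices
#'
#' The default granularity mirrors the in situ protocol: one
#' one-phase-association fit per cell from its own calibration plateaus,
#' the cell's baseline inverted through its own curve; cell estimates are
#' averaged per slice and the slice means averaged into the grand mean
#' (mean +/- SEM across slices). `pooled = TRUE` instead fits one curve to
#' all plateau points of a slice.
#'
#' @param trace_list list of per-slice trace tables
#'   (see [generate_sbfi_traces()]).
#' @param n_frames frames averaged per phase (default 3).
#' @param pooled fit one curve per slice instead of per cell.
#' @return list: `grand_mean` (mM), `sem` (across slices), `slice_means`,
#'   `cells` (`data.frame`: slice, cell, nai_mM, clipped), `n_failed`.
#' @export
estimate_nai_study <- function(trace_list, n_frames = 3L, pooled = FALSE) {
  if (!length(trace_list)) stop_config("no slices supplied")
  cells <- list(); n_failed <- 0L
  for (s in seq_along(trace_list)) {
    pl <- sbfi_plateau_table(trace_list[[s]], n_frames)
    cal_rows <- !is.na(pl$conc_mM)
    slice_cal <- if (pooled)
      fit_one_phase(pl$conc_mM[cal_rows], pl$fluorescence[cal_rows])
    for (cl in unique(pl$cell)) {
      d <- pl[pl$cell == cl, ]
      cal <- if (pooled) slice_cal else
        fit_one_phase(d$conc_mM[!is.na(d$conc_mM)],
                      d$fluorescence[!is.na(d$conc_mM)])
      base <- d$fluorescence[is.na(d$conc_mM)]
      est <- tryCatch(interpolate_nai(cal, base[1]), error = function(e) NULL)
      if (is.null(est) || isTRUE(cal$failed)) { n_failed <- n_failed + 1L
      } else {
        cells[[length(cells) + 1L]] <-
          data.frame(slice = s, cell = cl, nai_mM = est$nai_mM,
                     clipped = est$clipped)
      }
    }
  }
  cells <- do.call(rbind, cells)
  if (is.null(cells)) stop_config("all cell calibrations failed")
  slice_means <- tapply(cells$nai_mM, cells$slice, mean)
  list(grand_mean = mean(slice_means),
       sem = sd(slice_means) / sqrt(length(slice_means)),
       slice_means = as.numeric(slice_means), cells = cells,
       n_failed = n_failed)
}

#' Fit a Pade(1,1) electrode calibration
#'
#' Least-squares fit of the rational response `V(C) = (a + b C)/(1 + c C)`
#' to the calibration standards. With exactly three standards the fit is
#' the exact rational interpolant (solved as a linear system); with more,
#' the true least-squares optimum is found by profiling `c` (1-D search,
#' `(a, b)` linear at each candidate). Fits whose denominator changes sign
#' on the standard range (a pole) or whose curve is non-monotone there are
#' rejected.
#'
#' @param conc standard concentrations, mM (>= 3 distinct).
#' @param mV measured voltages.
#' @return object of class `isme_calibration`: `a`, `b`, `c`, `residual`,
#'   `conc`, `mV`.
#' @export
#' @examples
#' v <- 58 * log10(c(48, 96, 144, 192) / 144)
#' fit_pade11(c(48, 96, 144, 192), v)
fit_pade11 <- function(conc, mV) {
  conc <- as.numeric(conc); v <- as.numeric(mV)
  if (length(conc) < 3L || length(unique(conc)) < 3L)
    stop_config("at least 3 distinct standards required for a Pade(1,1) fit")
  if (length(conc) != length(v)) stop_config("conc/mV length mismatch")
  if (any(conc <= 0)) stop_config("standards must be positive")
  # denominator must stay positive on the standard range
  c_lo <- -0.999 / max(conc)
  if (length(conc) == 3L && length(unique(conc)) == 3L &&
      !anyDuplicated(conc)) {
    # exact interpolation: a + b C - c C V = V is linear in (a, b, c)
    A <- cbind(1, conc, -conc * v)
    sol <- tryCatch(unname(solve(A, v)), error = function(e)
      stop_config("standards are degenerate; no rational interpolant"))
    pars <- c(a = sol[1], b = sol[2], c = sol[3])
    resid <- 0
  } else {
    rss_c <- function(cc) {
      den <- 1 + cc * conc
      sum(lm.fit(cbind(1 / den, conc / den), v)$residuals^2)
    }
    grid <- seq(c_lo, 0.5, length.out = 60)
    i <- which.min(vapply(grid, rss_c, numeric(1)))
    opt <- optimize(rss_c, c(grid[max(1L, i - 1L)],
                             grid[min(length(grid), i + 1L)]), tol = 1e-12)
    cc <- opt$minimum
    den <- 1 + cc * conc
    ab <- lm.fit(cbind(1 / den, conc / den), v)$coefficients
    pars <- c(a = unname(ab[1]), b = unname(ab[2]), c = cc)
    resid <- opt$objective
  }
  rng <- range(conc)
  grid_c <- seq(rng[1], rng[2], length.out = 201)
  den_g <- 1 + pars["c"] * grid_c
  if (any(den_g <= 0))
    stop_config("fitted Pade(1,1) has a pole inside the standard range")
  vals <- (pars["a"] + pars["b"] * grid_c) / den_g
  if (is.unsorted(vals) && is.unsorted(rev(vals)))
    stop_config("fitted calibration is non-monotone on the standard range")
  structure(list(a = unname(pars["a"]), b = unname(pars["b"]),
                 c = unname(pars["c"]), residual = resid,
                 conc = conc, mV = v),
            class = "isme_calibration")
}

#' @export
print.isme_calibration <- function(x, ...) {
  cat(sprintf(
    "<isme_calibration> V(C) = (%.4g + %.4g C)/(1 + %.4g C), RSS %.3g\n",
    x$a, x$b, x$c, x$residual))
  invisible(x)
}

# fitted voltage of a calibration at concentration C
pade_value <- function(cal, conc) (cal$a + cal$b * conc) / (1 + cal$c * conc)

#' Interpolate an electrode voltage to extracellular sodium
#'
#' Subtracts the junction-potential offset and inverts the rational
#' calibration in closed form: `C = (V' - a)/(b - c V')`. Voltages outside
#' the fitted curve's span over the standard range error rather than
#' silently extrapolate; `tolerance_mM` widens the admissible concentration
#' range at both ends.
#'
#' @param cal an [fit_pade11()] calibration.
#' @param voltage recorded voltage(s), mV.
#' @param junction_offset bath-vs-tube junction potential, mV, subtracted
#'   before inversion (default 0).
#' @param tolerance_mM extrapolation allowance beyond the standard range
#'   (default 10 mM).
#' @return concentration(s), mM.
#' @export
interpolate_nae <- function(cal, voltage, junction_offset = 0,
                            tolerance_mM = 10) {
  stopifnot(inherits(cal, "isme_calibration"))
  vp <- voltage - junction_offset
  conc <- (vp - cal$a) / (cal$b - cal$c * vp)
  lo <- min(cal$conc) - tolerance_mM
  hi <- max(cal$conc) + tolerance_mM
  if (any(!is.finite(conc)) || any(conc < lo) || any(conc > hi))
    stop_config("offset-corrected voltage falls outside the calibrated ",
                "range [", signif(lo, 4), ", ", signif(hi, 4),
                "] mM; refusing to extrapolate")
  conc
}

#' Electrode sensitivity drift check
#'
#' Compares pre- and post-experiment calibrations by their sensitivity
#' dV/dC at a midrange concentration; drift is the relative change. The
#' routine QC bound is 5%.
#'
#' @param cal_pre,cal_post [fit_pade11()] calibrations.
#' @param at concentration (mM) at which to evaluate dV/dC (default 120).
#' @param tol pass bound on the drift fraction (default 0.05, inclusive).
#' @return list: `drift`, `pass`, `sens_pre`, `sens_post` (mV/mM).
#' @export
drift_check <- function(cal_pre, cal_post, at = 120, tol = 0.05) {
  stopifnot(inherits(cal_pre, "isme_calibration"),
            inherits(cal_post, "isme_calibration"))
  sens <- function(cal) (cal$b - cal$a * cal$c) / (1 + cal$c * at)^2
  s_pre <- sens(cal_pre); s_post <- sens(cal_post)
  drift <- abs(s_post - s_pre) / abs(s_pre)
  # inclusive bound with a float guard so an exactly-5% drift passes
  list(drift = drift, pass = drift <= tol * (1 + 1e-9) + 1e-12,
       sens_pre = s_pre, sens_post = s_post)
}

#' Estimate tissue extracellular sodium for a study of slices
#'
#' Per slice: fit the Pade(1,1) calibration to the pre-experiment standards
#' (or to pre and post jointly with `use = "both"`), subtract the junction
#' offset from each tissue recording, invert, and average; slice means are
#' averaged into the grand mean (mean +/- SEM across slices). When post
#' standards are present the sensitivity drift is checked per slice.
#'
#' @param recording_list list of per-slice recording sets
#'   (see [generate_isme_recordings()]).
#' @param junction_offset junction potential subtracted from tissue
#'   recordings, mV.
#' @param use `"pre"` (default) or `"both"`: standards used for the fit.
#' @param drift_tol QC bound passed to [drift_check()].
#' @return list: `grand_mean` (mM), `sem` (across slices), `slice_means`,
#'   `recordings` (`data.frame`: slice, recording, nae_mM), `drift`
#'   (per-slice drift fractions, `NA` without post standards),
#'   `drift_pass`.
#' @export
estimate_nae_study <- function(recording_list, junction_offset,
                               use = c("pre", "both"), drift_tol = 0.05) {
  use <- match.arg(use)
  if (!length(recording_list)) stop_config("no slices supplied")
  recs <- list(); slice_means <- numeric(0); drifts <- numeric(0)
  for (s in seq_along(recording_list)) {
    rl <- recording_list[[s]]
    std <- rl$standards
    pre <- std[std$stage == "pre", ]
    fit_std <- if (use == "both") std else pre
    cal <- fit_pade11(fit_std$conc_mM, fit_std$mV)
    drift <- NA_real_
    if (any(std$stage == "post")) {
      post <- std[std$stage == "post", ]
      cal_post <- fit_pade11(post$conc_mM, post$mV)
      cal_pre <- fit_pade11(pre$conc_mM, pre$mV)
      drift <- drift_check(cal_pre, cal_post, tol = drift_tol)$drift
    }
    nae <- interpolate_nae(cal, rl$tissue$mV, junction_offset)
    recs[[s]] <- data.frame(slice = s, recording = rl$tissue$recording,
                            nae_mM = nae)
    slice_means <- c(slice_means, mean(nae))
    drifts <- c(drifts, drift)
  }
  list(grand_mean = mean(slice_means),
       sem = sd(slice_means) / sqrt(length(slice_means)),
       slice_means = slice_means,
       recordings = do.call(rbind, recs),
       drift = drifts,
       drift_pass = ifelse(is.na(drifts), NA, drifts <= drift_tol))
}
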