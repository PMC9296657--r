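---
title: "Quantifying tumour sodium with 23Na MRI, DWI and ex vivo calibrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumour sodium with 23Na MRI, DWI and ex vivo calibrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natremri)
```

## The problem

Malignant breast tumours accumulate sodium. Non-invasive sodium
(\(^{23}\)Na) MRI reads total tissue sodium concentration as a signal
proportional to [Na\(^+\)], while proton diffusion-weighted imaging (DWI)
reads cellularity through the apparent diffusion coefficient (ADC): dense,
highly cellular tumours restrict water diffusion and show low ADC. The two
modalities are complementary — elevated tumour [Na\(^+\)] together with
reduced ADC points at *intracellular* sodium accumulation rather than an
expanded extracellular space — and combining them improves tumour vs
non-tumour classification.

`natremri` implements the full quantitative chain around these
measurements for preclinical (orthotopic mouse xenograft) studies: image
quantification, ADC mapping, classification, the ex vivo calibrations that
resolve intracellular ([Na\(^+\)]\(_i\)) and extracellular
([Na\(^+\)]\(_e\)) sodium, and the two-compartment mixture model that ties
everything together. Because raw animal imaging data are not
redistributable, a synthetic-data module generates every input with known
ground truth; it is first-class, tested code, and all pipeline guarantees
below are stated with respect to it.

## Sodium quantification

A scene contains a 50 mM NaCl reference phantom imaged alongside the
animal. Per subject, mean and maximum \(^{23}\)Na signal in each region of
interest (ROI: tumour, contralateral non-tumour, phantom) are divided by
the phantom ROI mean; multiplying the normalised signal by the phantom
concentration converts it to an apparent tissue concentration in mM:

\[ [\mathrm{Na}^+]_{roi} = \frac{\bar S_{roi}}{\bar S_{phantom}} \times 50\,\mathrm{mM}. \]

Two assumptions are made and documented rather than modelled: signal is
linear in concentration (empirically true for 0–100 mM at these settings),
and differential T1 saturation between tissue and phantom is ignored, so
the mM figures are phantom-referenced *apparent* concentrations.

Surface-coil acquisitions need a B1 correction first. The receive profile
is modelled as the radial gain \(g(x) = G/(d(x)+d_0)^2\), where \(d(x)\)
is the distance to the coil and the floor \(d_0 > 0\) (default search
range 0.25–100 mm) avoids the singularity at the coil plane. `b1_correct()`
fits \(G\) and \(d_0\) to a uniform 1 M NaCl reference image — by least
squares in log-signal space by default, which keeps the phantom's large
dynamic range from dominating the fit — and divides the target image by the
fitted gain normalised to unit mean, so overall scale (which the phantom
normalisation cancels anyway) is preserved. On noise-free synthetic scenes
the round trip gain-then-correct is exact to well under 1%.

The maximum-signal statistic is computed on the corrected but *unsmoothed*
image; a 3-D median filter (`median_filter3()`) is available but off by
default, because whether any smoothing preceded the original max statistic
is unknowable and the maximum is the more conservative reading without it.

Tumour volume comes either from the ROI (voxel count times voxel volume)
or from calliper measurements via the modified ellipsoid formula
\(V = \tfrac12 L W^2\); the two calliper inputs are sorted so that length
is the longer axis rather than erroring on mislabelled input.

## ADC estimation

Signal decays mono-exponentially with diffusion weighting,
\(S(b) = S_0 e^{-b\,\mathrm{ADC}}\), acquired here at
\(b = 0, 100, 300, 700\) s/mm\(^2\). With two b-values the classical
closed form \(\mathrm{ADC} = -\ln(S/S_0)/b\) applies; with more, the
package uses ordinary least squares of \(\ln S\) on \(b\) (the standard
multi-b generalisation, identical to the closed form for two points). All
pairwise two-point ADCs are emitted alongside for audit, since a
two-point protocol and a multi-b OLS differ under noise and the historical
choice cannot be recovered.

Voxelwise maps use the same fit vectorised over voxels. Voxels whose
signal touches the noise floor (default threshold 0; recommended
\(3\sigma\) of the background noise when known) are marked invalid and
excluded from ROI summaries rather than erroring, and the invalid fraction
is reported. Full tensor estimation is deliberately out of scope: only the
scalar ADC enters any downstream analysis.

## Classification

Features per region are the phantom-normalised maximum and mean
\(^{23}\)Na signal and the ADC. The classifier is linear discriminant
analysis written from its Gaussian definition: class means, pooled
within-class covariance with denominator \(n-2\), class-frequency priors
(an `equal` flag exists; frequency priors are the appropriate default for
the unbalanced test cohorts), posteriors by the shared-covariance Gaussian
likelihoods. Ties break toward the larger-prior class, then toward tumour,
so predictions are deterministic. Features are not standardised — LDA is
scale-equivariant.

Small cohorts make resubstitution accuracy meaningless, so accuracy is
estimated by leave-one-out cross-validation (`loocv()`), and independent
cohorts are scored with `evaluate_on_test()`. Tumour is the positive class
everywhere: sensitivity is the detected fraction of true tumour regions.
ROC curves sweep all score thresholds and the AUC is the trapezoid
integral, which equals the Mann–Whitney pair-win fraction with ties worth
one half. PCA (`pca_features()`) defaults to correlation scaling because
the features mix dimensionless signal with mm\(^2\)/s; loading signs are
fixed so each component's first nonzero entry is positive. The 95%
"concentration ellipse" around a class's scores is implemented as the
Gaussian covariance ellipse (`concentration_ellipse()`) and labelled as
such — a kernel-density contour is a different object.

On synthetic cohorts with the default effect structure (elevated
heterogeneous tumour sodium, reduced tumour ADC, negative pooled Na–ADC
correlation) the combined two-feature model's test accuracy is at least
each single-feature model's in the median over seeds, mirroring the
qualitative finding that the combination is the better malignancy marker.
The numeric accuracies of the original animal cohorts are functions of
unreleased data and are not targets of the synthetic study.

## Ex vivo calibrations

**SBFI / intracellular sodium.** Tumour-slice cells loaded with the
sodium-sensitive dye SBFI are calibrated in situ: ionophores (gramicidin,
monensin) plus Na\(^+\)/K\(^+\)-ATPase blockade equilibrate
[Na\(^+\)]\(_i\) with the perfusate, which is stepped through 10, 20 and
50 mM. The mean of the final three frames of each phase gives one plateau
per concentration; plateaus follow the one-phase association
\(Y(x) = Y_0 + (P - Y_0)(1 - e^{-Kx})\), and the resting baseline
fluorescence is inverted through the fitted curve,
\(x = -\ln(1 - (F-Y_0)/(P-Y_0))/K\). Fits are per cell (each cell's own
calibration controls for dye loading differences), cell estimates are
averaged per slice and slices into the grand mean, matching the
mean ± SEM structure of the ex vivo design (3 slices, 11–16 cells each);
a pooled per-slice fit is available by flag.

**Electrodes / extracellular sodium.** Ion-selective microelectrodes are
calibrated against 48/96/144/192 mM standards before and after recording;
the calibration curve is the Padé (1,1) approximant
\(V(C) = (a + bC)/(1 + cC)\), fitted as \(V\) on \(C\) and inverted in
closed form \(C = (V' - a)/(b - cV')\) after subtracting the junction
potential offset from each tissue voltage. Fits with a pole or a
non-monotone stretch inside the standard range are rejected. Sensitivity
drift between pre and post calibrations (dV/dC at 120 mM) is checked
against the routine 5% bound. Fitting \(C\) as a function of \(V\) would
give the same interpolant on exact-fit data but different noise behaviour;
the \(V(C)\) direction is the package's fixed choice.

**Numerics.** Both curve families are linear in all parameters but one
(\(K\), or the denominator coefficient \(c\)), so fitting uses variable
projection: a deterministic 1-D search over the nonlinear parameter (40
log-spaced candidates for \(K\) in \([10^{-4}, 1]\) per mM, 60 for \(c\),
each refined by golden-section search) with the linear parameters solved
exactly at each candidate. This is seedless, reproducible, and handles the
exact-interpolation three-point case that generic nonlinear optimisers
fail on. With three points and three parameters the fit interpolates the
noise, so \(K\) itself is ill-conditioned (roughly 13% spread per 1% of
plateau noise); the interpolated concentration is far better conditioned,
and the study-level averaging (3 frames, then cells, then slices) is what
delivers sub-mM precision.

**A known, deliberate mismatch.** The synthetic electrode responds
Nernstianly (\(V = s\log_{10} C/C_{ref}\), 58 mV/decade) while the
analysis fits a Padé (1,1), exactly as the real analysis imposed a
rational curve on a near-Nernstian electrode. The best rational
approximant through the four standards deviates from the log curve by
−0.14 mV at 157.8 mM, a systematic −0.9 mM under-read that no amount of
replication removes. The recovered grand mean therefore sits ~0.5% low of
truth — accurate at the study's reporting precision, but a structural
floor on this calibration's accuracy worth knowing about.

## Two-compartment model

Total tissue sodium mixes the two spaces:

\[ [\mathrm{Na}^+]_{tissue} = (1-\mathrm{EVF})\,[\mathrm{Na}^+]_i + \mathrm{EVF}\,[\mathrm{Na}^+]_e, \qquad \mathrm{EVF} = 1 - \mathrm{IVF}. \]

`solve_evf()`, `solve_nai()` and `forward_total()` give all directions in
exact algebra. For the measured tumour values — [Na\(^+\)]\(_i\) 25.9 mM,
[Na\(^+\)]\(_e\) 157.8 mM, total 46.9 mM — the solution is EVF 0.159, IVF
0.841; holding those fractions and solving for healthy mammary gland
(total 29.7 mM, [Na\(^+\)]\(_e\) 158 mM) returns
[Na\(^+\)]\(_i\) = 5.4 mM, inside the healthy physiological range.
Solutions outside \([0,1]\) (or negative concentrations) are returned
with `physiological = FALSE` rather than clamped: the model omits blood
and ductal compartments, so out-of-range output is diagnostic, not an
error. Reporting precision follows convention (fractions to 3 d.p.,
concentrations to 1 d.p., via `format_compartment()`); full precision is
kept internally.

## The synthetic-data module

Generators and their defaults define the study conditions:

* **Scene** (`scene_phantom_spec()`): 48×48×12 grid at 0.5×0.5×1 mm;
  spherical 50 mM phantom; ellipsoidal tumour at 46.9 mM mean with a
  smoothed Gaussian concentration texture (SD 5 mM — the real spatial
  structure of intratumoural sodium is uncharacterised, so the texture
  amplitude is a free, documented choice); background and contralateral
  non-tumour tissue at 29.7 mM; optional surface-coil \(1/r^2\) gain.
* **Noise**: Rician on magnitude images (the physically correct
  magnitude-MR model, sampled as the modulus of a biased complex Gaussian;
  the sampler is validated against the analytic Rician mean and a numeric
  integration of the density), Gaussian multiplicative on fluorescence,
  Gaussian additive on voltages. Default image noise σ = 1.5 signal units
  puts tissue SNR near 20–30, typical of preclinical \(^{23}\)Na work.
* **DWI** (`dwi_scene_spec()`): b = 0/100/300/700 s/mm\(^2\); tumour ADC
  0.7×10\(^{-3}\), background 1.6×10\(^{-3}\) mm\(^2\)/s, the accepted
  ranges for dense xenograft tumour vs healthy soft tissue.
* **Cohort** (`cohort_spec()`): 15 subjects per class, trivariate Gaussian
  per class over (max Na, mean Na, ADC) with within-class correlations
  (0.7 between the Na statistics, −0.4/−0.35 Na–ADC); between-class
  separation dominates, so the pooled Na–ADC correlation is strongly
  negative as observed in vivo.
* **Traces** (`sbfi_trace_spec()`, `isme_recording_spec()`): curve
  parameters \(Y_0 = 1\), Plateau 2, \(K = 0.05\)/mM; 2% frame noise;
  58 mV/decade electrode, 10 mV junction offset, 0.3 mV voltage noise,
  optional ≤5% sensitivity drift.

Everything is bit-reproducible given the spec's seed; each generator
restores the caller's RNG state.

What the generators do *not* emulate — partial-volume blur, k-space /
readout artefacts, motion, registration error between the \(^1\)H and
\(^{23}\)Na grids, T1/T2\(^*\) relaxation differences, dye leakage and
bleaching, electrode hysteresis — bounds what a passing suite shows: the
*analysis chain* is correct and stable under the stated noise models, not
that acquisition physics has been simulated.

## Problem sizes and test design

The checks run at the original study's ex vivo design sizes (3 slices ×
11–16 cells; 6 slices × 12 recordings; 50 replicates for recovery rates),
cohort sizes of 15–200 per class, and imaging grids of 48×48×12 (sodium)
and 32×32×8 (DWI) — compact scenes with ROIs comfortably above 100 voxels,
chosen so whole-suite Monte-Carlo remains cheap. Oracles are independent
by construction: direct-formula t and correlation statistics, pair-counting
AUC, a literal Gaussian-discriminant evaluator, numeric integration of the
Rician density, and exhaustive enumeration where the space is small enough
(all labellings up to n = 6 for the AUC).

## Known limitations

* Concentrations are phantom-referenced apparent values; no T1/T2\(^*\)
  correction is attempted.
* The B1 model is purely radial; real surface-coil profiles deviate from
  \(1/r^2\) off-axis.
* ADC is scalar and mono-exponential; no IVIM, kurtosis or tensor terms.
* The Padé (1,1) electrode calibration under-reads a truly Nernstian
  electrode by ~0.9 mM near 158 mM (see above).
* The compartment model ignores blood and ductal spaces and assumes the
  tumour-derived volume fractions transfer to healthy gland when solving
  for its [Na\(^+\)]\(_i\).
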