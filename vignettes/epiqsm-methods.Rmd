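---
title: "Simulating test-retest reliability of R2* and QSM with multi-shot 3D EPI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating test-retest reliability of R2* and QSM with multi-shot 3D EPI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiqsm)
```

## The question

Multi-echo T2*-weighted brain MRI underlies R2* relaxometry and quantitative
susceptibility mapping (QSM). Conventional 3D gradient-echo (GRE) acquisition
reads one k-space line per TR, so a 1 mm whole-brain scan takes minutes and
integrates several minutes of physiological B0 fluctuation and motion into
one image. Multi-shot 3D EPI reads several lines per echo per TR (the *EPI
factor*), shortening the scan proportionally without a parallel-imaging
g-factor penalty. `epiqsm` is an in-silico laboratory for the resulting
trade: faster scans collect less physiological corruption but, at matched
resolution, need a proportionally higher readout bandwidth and therefore pay
sqrt(bandwidth) in thermal noise per repetition — which is exactly recovered
by repeating the EPI scan EPI-factor times and averaging, the *matched-SNR*
design encoded in the protocol presets (`protocol_presets()`).

The package simulates that design end to end and measures test-retest
reliability the way the quantitative-MRI field does: the voxelwise
normalized absolute difference (NAD) of repeated magnitude images,
`NAD = |m1 - m2| / ((m1 + m2)/2)`, and the inter-scan absolute differences
`|dR2*|`, `|df|`, `|dchi|` of the fitted maps, summarized by empirical CDFs
and their medians.

## The forward model

**Phantom.** `build_phantom()` makes an analytic digital head: an
ellipsoidal white-matter brain (chi = -30 ppb, R2* = 21 /s), a CSF shell
(chi = 0, R2* = 1 /s), five spherical deep-grey nuclei (chi 60–180 ppb, R2*
35–75 /s) and three white-matter ROI spheres, all with literature-typical
values for brain tissue at 3 T; they are documented design choices of the
simulator, not measurements. Geometry is
analytic so every ROI has exact ground truth; ROI centres jitter by up to a
voxel per seed. The default grid is 64 x 64 x 48 at 3 mm: physics at desk
scale rather than the full 240 x 180 x 144 mm / 1 mm protocol matrix, which
is available through the presets when needed.

**Field.** `chi_to_field()` applies the standard k-space dipole kernel
`D(k) = 1/3 - kz^2/|k|^2` with `D(0) = 0` (zero-mean field; B0 along z,
gamma = 42.58 MHz/T). The kernel is validated against the analytic
uniform-sphere solution: the internal field vanishes and the external field
matches the point-dipole term to about a percent. A deliberate caveat: the
response to a *single-voxel* impulse is not the sampled analytic point
dipole — on a discrete grid the two disagree strongly near the source and
along the axes, so tests validate against smooth (sphere) sources.

**Physiology.** `sample_physio_timeline()` draws one state per shot (TR):
a global B0 offset composed of a random-walk drift (default 0.2 Hz per
shot) plus a respiratory sinusoid (1 Hz amplitude, 4 s period), an optional
spatially linear B0 term (default 0 Hz/mm; the correction machinery for it
is implemented and tested, but the default study conditions model the
dominant global fluctuation), and a rigid translation random walk (0.02 mm
per shot). No consensus magnitudes exist for these nuisance processes;
the defaults were chosen once to be plausible at 3 T — drift
accumulating to a few Hz over a minutes-long GRE scan — and are all
configurable. Because the drift is a random walk, a protocol's vulnerability
grows with its shot count: this is the physical mechanism behind every
reliability ordering the package reproduces, not a tuned outcome.

**Acquisition.** `simulate_scan()` synthesizes, per shot `s` and echo `e`,
the image `m0 exp(-R2* TE_e) exp(2 pi i (f_chi + f_s(r)) TE_e)`, applies the
shot's translation as a Fourier shift, takes a *unitary* 3D DFT and samples
the shot's phase-encode lines on the (optionally 2 x 2 CAIPI-staggered)
lattice, then adds circular complex Gaussian noise with per-component SD
`noise_sigma`; `thermal_noise_sigma()` scales that SD with sqrt(bandwidth)
between protocols. This is an inverse crime on purpose: simulation and
reconstruction share the discrete model, so reconstruction contracts are
testable to machine precision, and the reliability questions at stake
concern shot-timescale phase errors and noise, not trajectory fidelity.
Two exact code paths exist — a fast one (one FFT per echo plus per-line
phases) whenever no shot carries a phase-encode-direction linear B0 term,
and a per-line evaluation of the phase-encode transform as a matrix product
otherwise; they agree to numerical precision.

## Reconstruction

`reconstruct()` implements the two modes under comparison. *Uncorrected*
demodulates only the scan-average global B0 at each echo time. *Corrected*
undoes, per shot: the global offset (scalar phase — exact), the translation
(conjugate Fourier-shift phase — exact), the readout-direction linear B0
(hybrid-space ramp — exact), and a phase-encode-direction linear B0 by
spreading each line through the conjugate modulation kernel — first-order
accurate only, since the exact inverse would need the iterative
non-Cartesian reconstruction that is out of scope here; simulated linear
terms are small and the residual is documented (a few percent RMSE where
uncorrected error is tens of percent). The corrected mode accepts either
the simulation's true timeline (oracle correction, the upper bound used in
the headline analyses) or a navigator-style estimate from
`estimate_timeline()`, which fits `a + g.r` to per-shot low-resolution
phase maps at the nominal navigator echo time of 3.9 ms. EPI
odd/even-polarity phase errors are corrected by `epi_phase_correction()`
from a non-phase-encoded central-line calibration pair.

Undersampled single-coil data is density-compensated and zero-filled —
parallel imaging is deliberately not in the reliability path, and the
default experiment samples fully at desk scale. An optional synthetic
8-coil mode (`synth_coil_sens()`) with direct least-squares unaliasing of
the CAIPI lattice exists for completeness and is exercised on small grids
in the tests.

## Quantification

* `fit_r2star()` — voxelwise mono-exponential magnitude fit
  `S0 exp(-R2* TE)` by vectorized Gauss-Newton from a log-linear start;
  non-converged voxels fall back to the log-linear estimate and are
  flagged; negative rates are clipped and counted; a warning surfaces the
  known magnitude-fit underestimation regime when last-echo SNR falls
  below 10. The fit is cross-checked in the tests against
  Levenberg-Marquardt (`minpack.lm`) voxel by voxel.
* `frequency_map()` — weighted least-squares phase slope over `2 pi TE`
  after temporal unwrapping against the prediction from earlier echoes;
  weights `magnitude^2 * TE` (a standard weighted-echo-combination choice,
  documented here because several weighting conventions coexist in the
  field). Spatial unwrapping (`spatial_unwrap()`, a
  quality-guided flood fill, vectorized layer-by-layer) runs first on any
  echo that wraps inside the mask.
* `vsharp_background_removal()` — variable-radius spherical-mean-value
  filtering (largest sphere that fits per voxel, default radii 6 to 1
  voxel-equivalents), each radius band deconvolved with its own kernel
  under a truncation threshold (default 0.05). This is a declared
  simplification of the combined Laplacian-boundary-value + V-SHARP chain
  used with real data; the eroded mask it returns is the QSM-valid mask.
* `dipole_inversion()` — closed-form thresholded k-space division (TKD,
  threshold 0.2, with the standard correction for TKD's systematic
  amplitude underestimation: division by the mean k-space response of the
  truncated operator) or Tikhonov inversion; the result is referenced to a
  zero mean over the brain mask, exactly. This replaces the
  structure-guided iterative inversion used with real data — which is why
  no susceptibility noise floor is offered: `monte_carlo_noise_floor()`
  refuses `dchi`, since that quantity would be specific to the chosen
  regularization.

For the reliability path, maps are quantified **per repetition and then
averaged as maps** — never as averaged complex data — which is what makes
the averaging curves interpretable as noise-averaging curves.

## The reliability analyses

`run_experiment()` ties it together for each protocol x mode: two scans per
scan-pair seed, per-repetition quantification, one translation-only
coregistration per scan pair estimated on the echo/repetition-averaged
magnitude by Fourier phase correlation with sub-voxel phase-plane
refinement (`coregister_translation()`) and reused for all companion maps,
then NAD (echo- and repetition-averaged variant), `|dR2*|`, `|df|`,
`|dchi|`, empirical CDFs (`empirical_cdf()`: median = value at cumulative
fraction 0.5), averaging curves (`averaging_curve()`), and medians averaged
across pairs. Geometric distortion correction is *not* applied in the
test-retest path (it is protocol-specific); the desk-scale simulator also
does not displace voxels with the static field, so cross-protocol ROI
comparisons (`roi_consistency()`) need no unwarping here — with real data
they would, and the machinery is in the distortion module.

The thermal-only reference comes from `monte_carlo_noise_floor()`: complex
noise added to a noiseless reference image, quantified exactly like the
simulated scans (including map-domain repetition averaging). Closed forms
anchor the Monte Carlo: for two noisy copies of a signal S with Gaussian
noise SD sigma, the median NAD is `sqrt(2) qnorm(0.75) sigma / S ~ 0.954
sigma / S` (folded normal), and the median `|d|` of two estimates with
per-voxel SD s is `0.954 s sqrt(2)`.

What the defaults reproduce, as expectations over >= 20 scan-pair seeds at
64 x 64 x 48 (the problem size used throughout the acceptance analyses; a
single pair takes tens of seconds): uncorrected median NAD and `|dR2*|`
strictly decrease from GRE (= EPI factor 1) through EPI x3 to EPI x5;
corrected beats uncorrected at every protocol; corrected EPI x5 sits within
a quarter of its thermal floor; and thermal-only averaging curves fall as
`1/sqrt(N)`.

## Distortion and blurring evaluations

The EPI-specific image-quality costs are quantified separately, as pure
parameter studies. `pixel_shift()` encodes the full-train dwell model
`shift = df x ETL` (150 Hz x 10 ms = 1.5 px). `correct_distortion()`
resamples along the distortion axis (readout for GRE, first phase-encode
for EPI) with genuine cubic B-spline interpolation (prefiltered, mirror or
periodic boundaries), guarded against non-invertible warps.
`evaluate_correction()` is the delta-function probe: displace a discrete
delta by a known sub-pixel amount (band-limited shift), correct it with the
matching uniform field, then read off (a) the residual position from the
slope of the unwrapped Fourier phase — demodulated by the expected position
first, which avoids the +-pi ambiguity of a centre-grid impulse — and (b)
the effective voxel size as Nyquist over the frequency where the corrected
spectrum first drops 3 dB below DC. The -3 dB criterion is applied to the
*amplitude* spectrum (10^(-3/20)); amplitude-vs-power is a convention
choice, fixed here by documentation. An on-grid
delta scores exactly 1; integer shifts are exact; the maximum over shifts
0..2 px stays at or below 2 nominal voxels.

`t2star_blur_fwhm()` weights k-space lines by `exp(-t/T2*)` with time
mapped linearly 0..ETL across the phase-encode lines (sequential ordering;
interleaved ordering would produce ghost-like modulation rather than smooth
blur and is out of scope) and measures the FWHM of the magnitude PSF by
linear interpolation between discrete samples, a convention under which a
decay-free train gives exactly 1.0 voxel; the continuous-sinc convention
(decay-free limit about 1.21 voxels) is reported as an attribute for
transparency. T2* = 10 ms across a 10 ms train stays below 1.2 voxels.

## Numerical choices and degenerate inputs

Unitary DFTs throughout (noise SD is transform-invariant; Parseval exact).
Image origin at index N/2; k-space pattern indices in centred layout;
noise SD means per real/imaginary component. NAD excludes voxels whose
pair mean falls below `1e-12 x` the in-mask maximum; exclusions are
counted and reported. All-zero
voxels are flagged `NA` and excluded from medians. Random-number use is
seeded explicitly everywhere, callers' RNG state is restored, and derived
seeds stay far below 2^31. Disconnected unwrapping components keep
independent 2 pi offsets; QSM referencing subtracts the brain-mean exactly.

## What passing tests do and do not show

The generator emulates mono-exponential decay, dipole fields, global +
linear B0 fluctuation, translation motion and white thermal noise on an
analytic phantom — with matched simulation/reconstruction models. It does
not emulate rotation, flow, eddy currents, coil-array noise correlation,
T1 saturation, ramp sampling, trajectory errors, anatomical texture, or
real physiological spectra. Reliability orderings reproduced here therefore
demonstrate the *mechanisms* (scan-duration-dependent physiological
corruption vs bandwidth-dependent thermal noise, and their response to
shot-wise correction and averaging), not in-vivo effect sizes, which
depend on cohort, hardware and processing choices no phantom can stand
in for.
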