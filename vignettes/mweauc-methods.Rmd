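---
title: "Models and methods behind mweauc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mweauc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mweauc)
```

# The measurement being modelled

An analytical ultracentrifuge with multiwavelength emission detection
(MWE-AUC) records, while a sample sediments at up to 40 000 rpm, radial
scans in which every radial position carries a full fluorescence
emission spectrum. A confocal optical head excites the sample with a
405 nm or 520 nm laser focused to a ~40 um spot and collects the
emitted light through a multi-mode fibre into a spectrograph with a
1600-pixel EMCCD sensor. The result of one experiment is a time series
of radius x wavelength count matrices. Analysing them yields a
two-dimensional distribution c(s, lambda): how much signal sediments
with coefficient s and emits at wavelength lambda, which links
hydrodynamic size to spectral identity in a single run.

`mweauc` implements both halves of that chain:

* a forward model (sedimentation physics, confocal optics,
  inner-filter attenuation, grating dispersion, EMCCD detection) that
  generates realistic synthetic scan sets with known ground truth, and
* the analysis pipeline: regularized c(s) inversion per wavelength with
  algebraic systematic-noise elimination, assembly into c(s, lambda),
  species extraction, discrete-species global fits, and the
  instrument-performance computations used to qualify such a detector
  (radial calibration, z-scans, SNR regimes, dynamic range, radial
  resolution).

# Sedimentation-diffusion transport

The concentration field c(r, t) of a species in a sector-shaped cell
obeys the Lamm equation

$$\frac{\partial c}{\partial t} =
  \frac{1}{r}\frac{\partial}{\partial r}
  \left[ r \left( D \frac{\partial c}{\partial r}
  - s\,\omega^2 r\, c \right) \right],$$

with closed boundaries at the meniscus $r_m$ and the cell bottom
$r_b$. `solve_lamm()` discretises this with a finite-volume scheme on
the uniform radial scan grid: fluxes at cell faces use
exponential-fitted (Scharfetter-Gummel) weighting
$J = (D/h)\,[B(-\mathrm{Pe})\,c_i - B(\mathrm{Pe})\,c_{i+1}]$ with
$B(x) = x/(e^x - 1)$ and face Peclet number
$\mathrm{Pe} = v h / D$. This is exact for the steady state, reduces
to central differencing for small Pe and to upwinding for large Pe,
and never oscillates. Time stepping is an implicit theta scheme
(backward Euler by default), which is unconditionally stable at
40 000 rpm and keeps the solution nonnegative; the step is chosen so
the boundary advances at most ~0.4 cells per step. Because the face
fluxes telescope and vanish at the walls, the discrete sector mass
$\sum_i c_i r_i h$ is conserved to machine precision — the test suite
checks a 1e-6 bound. Grids with fewer than 20 radial points are
refused rather than solved badly.

Two closed forms serve as oracles: the diffusion-free boundary
position $r_m e^{s\omega^2 t}$ (`faxen_boundary()`) and the
square-dilution rule $c_p/c_0 = e^{-2 s \omega^2 t}$
(`radial_dilution()`). The solver tracks the first within one radial
step for an ideal boundary and the second within 0.1%.

Hydrodynamics follow c(s) practice: for given s, frictional ratio
f/f0 and partial specific volume $\bar v$, the equivalent compact
sphere has Stokes radius
$R_0 = \sqrt{4.5\, s\,\eta\,(f/f_0)\,\bar v / (1 - \bar v \rho)}$ and
$D = k_B T / (6 \pi \eta\, (f/f_0)\, R_0)$, so $D \propto s^{-1/2}$.
The Svedberg relation $M = sRT/(D(1-\bar v\rho))$ closes the loop and
is cross-checked against an independent root-finding construction in
the tests.

# The instrument model

`instrument_model()` collects the optics and detector parameters:

* **Confocal geometry.** The collection spot is the image of the
  signal-fibre core at fixed magnification 0.675 (a 200 um core gives a
  135 um spot, four times the 50 um core's). The confocal depth is
  anchored to the two characterised cores — 0.7 mm at 50 um and 1.5 mm
  at 200 um — with linear interpolation between them; the true
  dependence between these anchors is not characterised, which the
  function flags with a warning for other cores.
* **Radial response.** The excitation spot is a Gaussian with 1/e^2
  diameter `laser_spot_diameter` (40 um default); the collection
  acceptance is a flat-top of the collection-spot diameter. The radial
  point response is their product, so with the large (135 um) collection
  spot the response is set by the excitation spot alone — the property
  behind the ~40 um radial resolution. Along z the collection weight is
  a flat-top of width `confocal_depth`; these are the simplest shapes
  consistent with the instrument's characterisation, and no attempt is
  made to model aberrated profiles.
* **Inner-filter effects.** Primary: the excitation beam is attenuated
  with depth as $10^{-\varepsilon_{exc}\int_0^z c\,dz'}$; secondary:
  emitted light is reabsorbed on its way out as
  $10^{-\varepsilon_{em}(\lambda)\int_0^z c\,dz'}$. Both are
  Beer-Lambert closed forms on the z grid. They produce the
  characteristic z-scan phenomenology: dilute samples give a symmetric
  trapezoidal profile peaked at the cell centre, concentrated samples
  an asymmetric profile whose peak shifts toward the incident face.
  The 2.0 mm shift of the cell position under vacuum is modelled as an
  additive offset between commanded and physical z.
* **Dispersion.** Each grating maps its spectral window (400-937,
  515-643 or 525-558 nm for 150, 600, 1800 lines/mm) linearly onto the
  1600-pixel sensor and blurs with a Gaussian kernel of the grating's
  resolution (2.0, 0.51, 0.14 nm FWHM). The kernel is applied as
  per-bin Gaussian mass, so dispersion conserves total intensity up to
  window truncation, which is warned about. Emission below the
  long-pass filter cutoff (laser + 10 nm by default) is blocked.
* **Detection.** Counts are
  $\mathrm{clip}(\mathrm{round}((\mathrm{Pois}(N_e) +
  \mathcal{N}(0,\sigma_{read}))/g) + \mathrm{offset},\, 0,\, 65535)$
  with read noise 7 e- rms (1 MHz ADC) or 4 e- (100 kHz), gain 1 or
  4 e- per count, a stable 100-count electronic offset and a 16-bit
  ceiling. Dark current is neglected (exposures are capped at 500 ms).
  EM-multiplication excess noise, Raman scattering and photobleaching
  are out of scope.
* **Photon budget.** A single calibration constant,
  `photons_per_unit`, fixes the expected band-integrated
  photoelectrons per unit concentration per ms. Absolute quantum
  yields are not modelled; all concentrations are in
  signal-equivalent units.

`simulate_sv_dataset()` composes Lamm profiles with dispersed species
spectra and the detection chain, optionally injecting a fixed radial
signal pattern (TI noise), per-scan offsets (RI noise) and a linear
beam-drift ramp (a first-generation artefact, off by default). The
generator is deterministic given its seed, which is recorded with the
species table and injected noise in a ground-truth sidecar.

# Regularized c(s) inversion

`fit_cs()` inverts a single-wavelength slice against a kernel of
unit-loading Lamm solutions on a log-spaced s grid (150 values by
default, matching routine practice), sharing one frictional ratio and
partial specific volume across columns. Signal amplitudes are rescaled
to a maximum below 10 before fitting and scaled back on output.

**Systematic noise.** Time-invariant (a fixed radial pattern) and
radial-invariant (a per-scan offset) components are eliminated
algebraically: both span linear subspaces, and projecting data and
kernel columns onto their orthogonal complement is double centering of
the radius x scan matrix. Given the amplitudes, the noise components
are then solved exactly from the residual means. TI and RI share a
constant direction; the package resolves the degeneracy by reporting
TI with zero mean over the analysis window.

**Nonnegative least squares.** The projected problem is compressed to
its normal equations, Cholesky-factored, and solved with the
Lawson-Hanson active-set algorithm; a final exact solve on the active
set removes compression round-off, so the result matches brute-force
dense NNLS to 1e-8 on toy problems. The compression makes the
per-wavelength cost of a multiwavelength analysis essentially one
matrix-vector product, which is what lets the kernel be computed once
and reused across all wavelengths.

**Regularization.** Second-derivative (Tikhonov) smoothing is applied
through augmented normal equations; a maximum-entropy variant with a
uniform prior is available and solved by bounded quasi-Newton descent.
The penalty weight is the largest one whose residual sum of squares
stays within the one-sided F bound
$\mathrm{rss}(\alpha) \le \mathrm{rss}(0)\, F_{p}(n, n)$ at confidence
p = 0.683 (one sigma) with n the number of fitted points, found by
bisection on log alpha to 0.1% relative tolerance. In this convention
a higher confidence level admits a larger chi-square ratio and hence
stronger smoothing — the standard usage in c(s) analysis; exactly-fit
(noise-free) data receive no penalty.

**Peak extraction.** Species are contiguous regions of the s grid
above 5% of the distribution maximum, reported with signal-weighted
mean s. A region containing several local maxima is split at interior
valleys deeper than 50% of the smaller neighbouring maximum: partially
resolved peaks — precisely the situation for species a few grid steps
apart under second-derivative smoothing — would otherwise merge into
one nominal species even when the distribution is clearly bimodal.
Both thresholds are exposed as arguments.

A deliberate consequence of the 0.683 smoothing criterion, confirmed
by the tests: species ~15% apart in s that the penalty-free inversion
separates sharply are merged by second-derivative regularization into
one broad peak, while a monomer/dimer pair ~50% apart stays baseline
separated. Closely spaced species are a recognised blind spot of this
regularizer; alternative schemes are out of scope here.

**Nonlinear parameters.** `optimize_nonlinear()` floats exactly one of
meniscus, f/f0 or vbar by Brent search on a bounded interval,
re-solving the linear problem at every trial. The scan objective is
the unregularized rmsd (fast and sufficient for location); the final
refit is regularized. A start value (e.g. vbar = 0.4 for dense
nanoparticles) is folded into the search interval, and optima pinned
at an interval end raise a warning.

# The multiwavelength layer

`fit_cs_lambda()` runs consecutive, mutually independent per-wavelength
fits (default analysis step 1.5 nm) against one shared kernel; results
are invariant under wavelength processing order, and TI/RI noise is
fitted independently per wavelength. The shared vbar is meant to be
fixed once — e.g. optimised on the wavelength-integrated signal — and
held constant across wavelengths.

`extract_species()` finds peaks on the wavelength-integrated c(s); a
species' emission spectrum is the amplitude slice summed over its
s-support and its emission maximum is located by quadratic
interpolation around the spectral maximum, giving sub-grid accuracy
well below one resolution element for smooth bands.

`global_species_fit()` fits K discrete s values shared across selected
wavelengths (nonlinear, Nelder-Mead on log s) with per-wavelength
nonnegative amplitudes and TI/RI elimination (linear, solved exactly
per trial). Start values are the mass quantiles of the integrated
c(s) at probabilities (i - 1/2)/K — robust when peaks are merged or
partially resolved, where peak picking alone would misplace starts.
Nearly coincident fitted s values (within 1%) are flagged as a sign
that K exceeds the number of identifiable species.

When species of genuinely different vbar are fitted with one shared
vbar and f/f0, the apparent s of a species drifts with wavelength
wherever spectra overlap — the shifts disappear when the generator and
kernel parameters match. The test suite reproduces this artefact
qualitatively.

# Instrument QC computations

* **Radial calibration.** Gap edges of a fluorescent-backed
  calibration disk are detected by 50% threshold crossing with
  hysteresis (30/70% state thresholds reject noise chatter) and
  sub-step interpolation; regressing known on detected positions gives
  the absolute offset and the step-size scale. Dense calibration
  sweeps (10 um) remove the phase-dependent interpolation bias of the
  50 um sedimentation-scan step.
* **Offset-induced s error.** `sedimentation_error_from_offset()`
  simulates a noise-free boundary, tracks its half-plateau midpoint,
  refits s from the slope of ln(r) versus omega^2 t with and without
  the offset, and agrees with the first-order closed form
  $\delta\,(1/r_m - 1/r_b)/\ln(r_b/r_m)$ within 10% for offsets up to
  200 um. A 100 um offset gives ~0.16%, below the 0.2% accuracy
  budget.
* **Radial resolution.** `edge_response_width()` reports the
  interpolated 10-90% rise of a scan across a sharp fluorophore step.
  On a 50 um grid the measured width depends on where the edge falls
  between samples (from ~40 um midway between samples up to ~80 um on
  a sample); `simulate_edge_scan()` therefore places the step midway
  between samples by default so the width reflects the optical
  response, ~40 um with the default geometry — and demonstrably
  independent of the 135 um collection spot.
* **SNR regimes.** `snr_characterize()` fits log-log SNR slopes below
  10 counts (read-noise regime, slope 1) and over 100-10 000 counts
  (shot regime, slope 1/2); the fitted regime lines intersect near
  sigma_read^2 photoelectrons. Over the finite 100-10 000 window the
  model's exact slope is ~0.54 because read noise still contributes at
  100 counts.
* **Dynamic range.** `linearity_range()` takes the concentration
  series 1.0 to 0.0001 mg/L crossed with exposures up to 500 ms, at
  both ADC gain settings (gain switching is how the instrument extends
  its range), and reports the widest contiguous log10 span of mean
  amplitude that is significant (SNR of the mean >= 3 over the
  replicate reads), unsaturated (below 95% of the 16-bit ceiling), and
  on a pooled log-log response slope within 1 +/- 0.02 (fitted with
  SNR^2 precision weights). Each grid point uses 2000 replicate reads
  by default — the equivalent of one full radial scan (~240 points)
  repeated over ~8 scans, which is how such a point is actually
  measured. The measured span is ~5.5 decades.
* **Band integration.** `band_integration_gain()` compares band-summed
  to peak-pixel SNR; for the 487-pixel 485-650 nm band of a
  coumarin-like spectrum at low amplitude the gain is of order 10,
  bracketed by the read-limited (S ratio / sqrt(N)) and shot-limited
  (sqrt of S ratio) bounds. The exact value depends on the band shape,
  so the check is qualitative.
* **Z-scan triage.** `assess_zscan()` summarises a z-scan by the
  asymmetry index 2 (z_peak - z_centre)/depth, with the peak taken as
  the centre of the near-maximum region (the confocal flat-top makes
  dilute profiles trapezoidal). |index| <= 0.15 classifies as
  "suitable"; the threshold is a package choice, configurable, as the
  underlying criterion is qualitative.

# Degenerate inputs and numerical choices

All-zero data give a zero distribution (not an error); zero-signal
z-scans classify as "no signal"; peaks at a scan boundary classify as
"scan range insufficient"; saturation is a value, never an error;
singular design matrices (e.g. an s grid entirely outside the data's
sensitivity) raise a diagnostic. Bisection tolerances are 1e-3
relative on the penalty weight and 50 iterations; Brent runs at 1e-4
of the interval width. The analysis window excludes the last 0.1 mm
at the cell bottom by default; in practice the back-diffusion
accumulation broadens as sqrt(D t) and can saturate the ADC, so
analyses in this package's own tests use windows ending a few mm above
the bottom, exactly as an analyst would choose interactively.

# What the synthetic data do and do not establish

The generator reproduces the structure of real multiwavelength runs:
50 um radial steps, consecutive scanning with per-scan times, spectra
on the active grating's pixel grid, shot/read/quantisation noise with
offset and 16-bit clipping, injected TI/RI components, inner-filter
distortion, and calibration and z-scan fixtures. It does not emulate
mechanical vibration, EM-multiplication excess noise, Raman
backgrounds, photobleaching, concentration-dependent sedimentation or
hydrodynamic non-ideality. Passing recovery tests therefore show the
analysis chain is correct and self-consistent under the stated noise
model — not that every systematic effect of the physical instrument is
benign.

Problem sizes in the test suite are chosen for fast, deterministic
checks: s grids of 8-80 values, 12-60 scans, narrow wavelength ranges
at 5-10 nm steps for single-band analyses and 6 nm for the
two-species 2D fixture. The defaults (150 s values, 1.5 nm step, full
grating window) match routine analyses of real runs and simply take
proportionally longer.
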