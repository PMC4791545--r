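---
title: "Time-stretch quantitative phase imaging: models, parameters, and design choices"
author: "tsqpi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-stretch quantitative phase imaging: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement this package models

Time-stretch quantitative phase imaging (TS-QPI) is a line-scan imaging flow
cytometry technique. A broadband laser pulse is spatially dispersed into a
"rainbow flash" whose wavelengths address distinct lateral positions across a
microfluidic channel, so one pulse captures one line image of whatever flows
past. The rainbow is split into the two arms of a Michelson interferometer;
the sample arm passes through the cell (twice, by reflection off the channel
substrate) while the reference arm sets up spectral interference. Time-stretch
dispersive Fourier transform then maps the pulse spectrum onto time, and a
single fast photodetector digitizes the result: each 27 ns repetition period
carries a spectral interferogram whose baseband envelope encodes optical loss
and whose ~4.7 GHz fringe carrier encodes optical phase.

`tsqpi` implements the whole computational chain in both directions:

* **Forward** (`optical_config()`, `cell_phantom()`, `synthesize_stream()`):
  simulate photodetector waveforms for populations of spherical cell
  phantoms.
* **Inverse** (`demodulate()`, `reconstruct_images()`): band separation,
  Hilbert-transform phase retrieval, unwrapping, background removal,
  calibration-free transmittance, and assembly into co-registered optical
  path difference (OPD) and loss images.
* **Analysis** (`segment_cells()` through `clean_records()`): segmentation,
  declumping, quality control, the 16-feature biophysical fingerprint, and
  table cleaning.
* **Learning** (`ga_train()`, `crossval()`, `baselines()`): a 16-48-48-48-1
  ReLU network with sigmoid output trained globally by a genetic algorithm on
  a regularized AUC cost, with ROC analysis, balanced accuracy, and
  conventional baselines.

# Forward model

## Field model and fringe carrier

At each wavelength (equivalently, lateral position `x`), the detected
intensity of one line scan is

$$I(t) = I_b(t) + I_i(t)\cos\!\big(2\pi f t + \varphi_c(x(t)) + \varphi_0\big),$$

with (for beam-split fraction $\alpha$, substrate reflectance $R$,
single-pass buffer power transmittance $T_s$, and cell single-pass field
transmittance $t_c$):

$$I_b = \alpha(1-\alpha)\,P(\lambda)\,R\,(T_s^2 t_c^4 + 1), \qquad
  I_i = 2\alpha(1-\alpha)\,P(\lambda)\,R\,T_s\,t_c^2 .$$

$P(\lambda)$ is the input pulse envelope: flat over the 1581-1601 nm band
with raised-cosine edges on 5% of the band at each side, matching a band
chosen where the source spectrum is flat. The cell phase is the double-pass
optical path difference, $\varphi_c = (2\pi/\lambda_c)\,2\Delta n\,t(x)$,
where $t(x)$ is the sphere chord.

Two chirped copies of a pulse delayed by the arm mismatch $\Delta L$ beat at

$$f = \frac{2\Delta L}{\lambda_c^2\,D'},$$

with $D'$ the total group delay slope (ns/nm). The package defaults to
$D' = 1.2$ ns/nm, stretching the 20 nm band to 24 ns inside the 27.3 ns
repetition period, and back-computes $\Delta L$ (7.14 mm) so the carrier
lands at 4.7 GHz. The 50 GS/s sampling rate then resolves the carrier with
~10.6 samples per period.

## Optical resolution in the forward model

The encoded phase and transmittance profiles are low-pass filtered with a
Gaussian point-spread function whose FWHM is the configured optical
resolution (2.5 um, `optical_resolution`). This is not a convenience: a
sphere's chord has infinite slope at its rim, and without the PSF the
instantaneous fringe frequency diverges there, which no demodulator could
invert. The attached ground truth is the post-PSF profile, which is the
physically observable quantity; against it, noise-free demodulation recovers
phase to about 0.4% of peak.

## Noise and determinism

Noise is additive Gaussian on the detected intensity with standard deviation
`noise_sigma` times the empty-frame baseband peak (relative intensity noise).
Amplifier-specific noise statistics are out of scope. All stochastic steps
(noise, the per-stream initial fringe phase $\varphi_0 \sim U[0, 2\pi)$,
population draws, GA) are driven by explicit integer seeds; identical seeds
give bit-identical waveforms.

# Inversion

* **Synchronization**: windows of `round(period * sampling_rate)` samples;
  the period comes from the configuration or from an FFT autocorrelation
  estimate (`estimate_pulse_period()`), which agrees with truth to about one
  sample on clean streams.
* **Band separation** (`split_bands()`): zero-phase FFT filter, unity below
  and zero above a 0.2 GHz raised-cosine transition centered at the 3 GHz
  cutoff — midway between the <1.6 GHz baseband content implied by cell
  transit times and the 4.7 GHz carrier. The two bands sum exactly to the
  input.
* **Phase** (`analytic_phase()`, `unwrap_phase()`): the argument of the
  FFT-constructed analytic signal, unwrapped by bringing consecutive
  differences into $(-\pi, \pi]$. Unwrapping output minus input is everywhere
  an integer multiple of $2\pi$. Note that increments of magnitude $\geq \pi$
  between samples are fundamentally ambiguous to any 1-D unwrapper; the
  carrier is sampled densely enough that real increments stay well below
  that.
* **Background removal** (`remove_background()`): subtract the unwrapped
  phase of an empty frame from the same stream (cancelling the fringe ramp
  and $\varphi_0$), then subtract the per-scan median, which absorbs both any
  $2\pi$ branch offset and slow drift; off-cell samples dominate the median.
  The outer 5% of the band at each edge is excluded from phase statistics
  (Hilbert edge artifacts).
* **Transmittance** (`extract_transmittance()`): with the reference-arm-only
  recording $I_{ref}$ and an empty frame $I_{empty}$,
  $T_c = (I_{cell} - I_{ref})/(I_{empty} - I_{ref})$. Every instrument factor
  cancels, so the recovery is exact without knowing $\alpha$, $R$, or $T_s$
  (verified by sweeping them in simulation). $T_c$ is reported as the
  **round-trip power factor** $t_c^4$; whether a "cell transmittance" means
  single-pass or round-trip power is a convention, and this is the one the
  extraction formula naturally produces. Samples where the denominator falls
  below 5% of its maximum are masked.

# Image reconstruction

Line scans become image columns; the row axis is the rainbow (130 um over
1200 band samples, pitch 0.108 um) and the column axis is flow
(`flow_speed / repetition_rate` = 0.0355 um per scan). Groups of
`y_decimation` consecutive scans are averaged per column; the default (3)
makes pixels near-isotropic (0.107 um). OPD is $\varphi_c \lambda_c / 2\pi$
using the center wavelength everywhere — the per-pixel wavelength deviates by
under 0.7% across the band. The per-scan baseband energy relative to its
rolling mean over a 1 us window (~37 pulses) is kept as a line gain for
pulse-to-pulse fluctuation calibration.

# Feature extraction

Segmentation smooths the OPD image with a Gaussian of
$\sigma = \text{resolution}/2.355$ (suppressing artifacts below the
resolution limit), thresholds at Otsu's between-class-variance maximum
(256-bin histogram), and labels 8-connected components. Note that thresholds
inside an empty histogram gap tie exactly on the Otsu criterion; the
implementation (EBImage) returns the gap midpoint, and the test oracle
therefore compares achieved variance rather than threshold location. Clumps
are split by a watershed on the smoothed intensity whose tolerance is 10% of
the image maximum (object centers = well-separated local maxima). Objects
touching the image border are discarded; objects with equivalent diameter
below 3 um (the smallest cell size of interest) or moment-ellipse aspect
ratio above 5 are removed as debris — numeric limits chosen once as what a
cytometrist would call dust, bubbles, or streaks. Tight masks are dilated by the 2.5 um optical resolution into
loose masks within which intensities are measured, since the PSF pushes cell
signal beyond the segmented boundary.

Choices worth calling out:

* **Diameter calibration.** An Otsu cut at fraction $h$ of a spherical
  phase profile's peak crosses it at extent $d\sqrt{1-h^2}$; the reported
  Diameter-RB/FL divide this factor out (exact for unblurred spheres,
  approximate under the PSF).
* **Refractive index.** The mean index contrast (protein-concentration
  proxy) is *not* computed from the thresholded diameter: the $d^3$ in the
  sphere volume turns a 10% diameter bias into a ~30% index bias. Instead
  `sphere_fit_opd()` solves for $(d, \Delta n)$ jointly from the
  blur-invariant OPD integral and the peak OPD, whose PSF attenuation
  $\beta(d, \sigma)$ is computed by quadrature. On noisy phantom populations
  the population-mean contrast lands within ~4% of truth. The plain
  integral/volume estimator remains available as
  `mean_refractive_index()`.
* **Perimeter and circularity.** Perimeter is the boundary chain-code length
  with Kulpa weights plus a $\pi$ half-pixel offset; with it, the
  circularity $4\pi A / P^2$ of digitized disks converges to 1, which raw
  boundary-pixel counts do not (they give ~1.23 or ~0.62 depending on
  convention).
* **Loss features.** Table-style loss features come in an
  absorption-dominant flavor (per-pixel attenuation coefficient
  $-\log T_c / (2t)$ with $t$ the OPD-implied thickness; mean and
  mean-absolute) and a scattering-dominant flavor (per-pixel $1 - T_c$;
  mean and mean-absolute), each calibrated by the input power envelope and
  the 1 us line gain. Several loss definitions are defensible for this
  instrument class; these four are the package's recorded choices.

Cleaning removes records with negative integrated phase first (bubbles,
turbulence, recognition errors), then computes Hotelling's $T^2$ on the
standardized, pooled 16-feature matrix and drops the top 2% (ceiling count).
Pooling across classes (rather than per class) is the package's choice.
Below 50 records the outlier pass is skipped with a warning; a singular
covariance is ridge-regularized ($10^{-6}$ of the mean diagonal).

# Learning

The classifier is a fully connected 16-48-48-48-1 network, ReLU hidden
units, sigmoid output, a bias node of value 1 per layer. Training is global:
a genetic algorithm (tournament size 3, uniform crossover rate 0.7, per-gene
Gaussian mutation at rate 0.05, elitism 1, weights initialized N(0, 0.1))
minimizes

$$C = (1 - \mathrm{AUC}) + \lambda\,\overline{w^2},$$

the mean square running over non-bias weights, with $\lambda = 10^{-3}$ by
default (validation-based selection from a grid is available via
`ga_control(select_lambda = TRUE)`). AUC has no useful gradient, which is
what motivates evolutionary search. Because the cost is piecewise constant
in the ranks, the mutation scale anneals (halving after five stalled
generations) so late generations can fine-tune. A stratified 20% validation
split drives early stopping and model selection; ties in validation AUC —
routine when the validation subset is small — break on training cost.

ROC curves come from three provably equivalent routes, and the equivalence
is asserted in the tests: scanning the output-layer bias weight (each shift
is one member of a classifier collection sliding along the decision
boundary's normal), scanning a threshold on the fixed model's
scores, and the Mann-Whitney rank statistic. Balanced accuracy is
$(\mathrm{TPR} + \mathrm{TNR})/2$ at the validation-ROC point nearest
$(0, 1)$. Cross-validation is stratified 5-fold with a validation subset
inside each training portion. Baselines (Gaussian-kernel SVM, logistic
regression, naive Bayes, and a backpropagation network trained on cross
entropy — `nnet`'s single-hidden-layer network, the environment's canonical
backprop implementation) run on identical folds with the same
operating-point rule.

**A structural limitation, found empirically and kept honest.** The
regularizer cannot penalize rank-overfitting: ReLU networks are positively
homogeneous and AUC is rank-invariant, so all weights can be scaled down to
shrink $\overline{w^2}$ without changing a single rank. On two-Gaussian data
with $d' = 4$ (Bayes AUC 0.998) the trained network reaches test AUC
0.97-0.99 but not reliably beyond, at any population/generation budget
tested; training AUC hits 1.0 within ~30 generations and the residual gap is
small-sample rank-overfit, not under-optimization. The test suite therefore
asserts near-Bayes learning (AUC $\geq$ 0.95) on that benchmark and full
stability on truly separable data ($d' = 6$: per-fold AUC spread < 0.05 at
n = 500).

# The synthetic demonstration and what it does (not) show

`demo_two_populations()` runs the full chain on two phantom classes —
class A: $d \sim N(8, 1)$ um, $\Delta n \sim N(0.018, 0.002)$, single-pass
field transmittance ~0.97; class B: $d \sim N(13, 1.5)$ um,
$\Delta n \sim N(0.024, 0.002)$, ~0.92 — at 1% relative intensity noise,
with 20 cells per class by default (about 13,000 line scans, ~2 minutes of
compute; the record count is sized to keep the whole suite interactive, and
`synth_cell_records()` generates feature-space records when only the
learning stage is under study, e.g. 1000 records for the cleaning and
null-label experiments). Labels are recovered by matching segmented
centroids to ground-truth flow positions. The demonstration reproduces the
central qualitative ordering — the multivariate test AUC is at least the
best single feature's test AUC — and the null variants (permuted labels,
zero effect size) sit at chance.

The generator emulates: spectral interference with a realistic carrier,
PSF-limited resolution, shot-like intensity noise, size/index/loss
heterogeneity within classes, clumps and debris (as explicit fixtures).
It does not emulate: non-spherical or textured real cells beyond a simple
roughness knob, wavelength-dependent substrate/buffer spectra (supported as
inputs but defaulted flat), flow-speed fluctuation, amplifier noise
statistics, or the measured nonuniform rainbow wavelength distribution
(exposed as an optional warp, identity by default). Passing tests therefore
certify the computational chain — not instrument-level performance on real
cells, whose published accuracies are out of scope here.

# Numerical choices

* Band-limited operations use length-preserving FFTs; the band split is
  exactly complementary, so reconstruction is lossless by construction.
* Envelope extraction: moving max minus min over one carrier period plus one
  sample, halved, then mean-smoothed over the same window.
* Degenerate inputs: all-zero carrier (undefined phase), empty masks, blank
  images, one-class label vectors, and sub-50-record cleaning all error or
  warn explicitly rather than returning silent nonsense.
* Problem sizes in tests: single pulses for round-trip checks; 20-seed
  repeats for noisy recovery; 1000-record tables for cleaning and null
  learning; the full demo at 20 cells/class. These sizes are the package's
  own benchmark conditions and are stated in the tests.
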