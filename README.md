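# tsqpi

Simulation, reconstruction, and machine-learning analysis for **time-stretch
quantitative phase imaging (TS-QPI)** — line-scan imaging flow cytometry in
which a spatially dispersed "rainbow" pulse interrogates flowing cells
through a Michelson interferometer and the pulse spectrum is stretched onto
time for single-photodetector capture. Each ~27 ns pulse is one line image:
its baseband envelope carries optical loss, and a ~4.7 GHz interference
fringe carries optical phase.

The package is for scientists who want a tested, end-to-end computational
chain for this class of instrument: a forward simulator to generate
photodetector waveforms from known cell phantoms, the inversion that turns
waveforms into quantitative optical path difference (OPD) and loss images,
cell-level feature extraction, and a classification stage built around a
genetic-algorithm-trained neural network that directly maximizes the area
under the ROC curve.

## The core models

**Signal model.** Within a line scan,
`I(t) = I_b(t) + I_i(t) cos(2π f t + φ_c(x(t)) + φ_0)`, where the fringe
carrier `f = 2ΔL / (λ_c² D')` is set by the interferometer arm mismatch ΔL
and the stretch dispersion D'. A cell adds the double-pass phase
`φ_c = (2π/λ_c) · 2Δn · t(x)` (sphere chord `t`) and attenuates the
sample-arm field. Demodulation separates the bands at 3 GHz, takes the
Hilbert-transform analytic phase, unwraps it, removes the empty-frame
background, and recovers the cell's round-trip transmittance
calibration-free as `T_c = (I_cell − I_ref)/(I_empty − I_ref)`.

**Features.** Sixteen per-cell features in three families — morphology
(diameters along rainbow/flow, areas, perimeter, circularity `4πA/P²`,
moment-ellipse axis and orientation, median radius), optical phase
(integrated OPD raw and gain-calibrated, mean refractive-index contrast via
a sphere + PSF fit), and optical loss (absorption- and scattering-model
means and absolute means). Tables are cleaned by negative-phase debris
removal followed by Hotelling T² trimming of the top 2%.

**Learning.** A 16-48-48-48-1 ReLU network with sigmoid output, trained
globally by a genetic algorithm minimizing `(1 − AUC) + λ·mean(w²)`, with
ROC by bias scan (provably equal to a threshold scan and to the
Mann-Whitney statistic — asserted in the tests), balanced accuracy at the
validation operating point, stratified 5-fold cross-validation, and SVM /
logistic-regression / naive-Bayes / backprop-DNN baselines on identical
folds.

## Worked example

Simulate one 10 µm cell (Δn = 0.02, single-pass field transmittance 0.95)
flowing through the default instrument at 1% intensity noise, reconstruct
the image pair, and measure it:

```r
library(tsqpi)

cfg <- optical_config(noise_sigma = 0.01)
cfg
#> <optical_config>
#>   band: 20 nm @ 1591 nm (fractional 1.3%)
#>   repetition: 36.6 MHz (period 27.32 ns, 1366 samples at 50 GS/s)
#>   stretch: 1.2 ns/nm -> band duration 24.0 ns
#>   fringe: 4.700 GHz (arm mismatch 7138 um)
#>   field of view: 130 um, flow 1.3 m/s, resolution 2.5 um

ph <- cell_phantom(center_x = 65, center_y = 7, diameter = 10,
                   delta_n = 0.02, amplitude_transmittance = 0.95)
train <- synthesize_stream(cfg, list(ph), seed = 1)
train
#> <pulse_train> 451 pulses x 1366 samples (27.32 ns period, 50 GS/s)

img <- reconstruct_images(train)
img
#> <quant_image_pair> 1200 x 150 px (pitch 0.108 x 0.107 um)

seg <- qc_filter(declump(segment_cells(img)), img)
rec <- measure_cells(seg, img)
round(rec[, c("Diameter-RB", "Refractive index", "Scattering-1",
              "Circularity")], 4)
#>   Diameter-RB Refractive index Scattering-1 Circularity
#> 1     10.1376           0.0208       0.0921      0.9983
```

The measured diameter (10.14 µm) and index contrast (0.0208) recover the
phantom's ground truth (10 µm, 0.02) to within the stated tolerances; the
mean loss over the loose boundary (0.092) reflects the cell's true
round-trip loss (0.185) diluted over the expanded measurement region; the
circularity of a sphere is ~1.

For the full chain — two phantom populations, feature ranking,
cross-validated AUC network, baseline comparison, PCA view — run
`demo_two_populations(seed = 1)` (about two minutes), or the command-line
front end:

```sh
Rscript inst/scripts/tsqpi demo --seed 1 --out report.json
```

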