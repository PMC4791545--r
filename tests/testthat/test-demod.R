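# Demodulation: synchronization, band split, envelope, Hilbert phase,
# unwrapping, background removal, transmittance.

test_that("pulse segmentation windows the stream exactly", {
  cfg <- test_cfg()
  tr <- synthesize_stream(cfg, list(), n_pulses = 10, seed = 1)
  scans <- segment_pulses(tr)
  expect_equal(dim(scans), c(1366, 10))
  one <- synthesize_stream(cfg, list(), n_pulses = 1, seed = 1)
  expect_equal(ncol(segment_pulses(one)), 1)
})

test_that("autocorrelation recovers the repetition period", {
  cfg <- test_cfg()
  tr <- synthesize_stream(cfg, list(cell_phantom(65, 1.5, 6, 0.02, 0.9)),
                          n_pulses = 60, seed = 2)
  est <- estimate_pulse_period(tr$samples, cfg$sampling_rate)
  expect_lt(abs(est - tr$pulse_period) * cfg$sampling_rate, 1.5)
})

test_that("band split separates carrier from baseband and reconstructs", {
  fs <- 50
  t <- (0:1999) / fs                 # 4.7 and 0.5 GHz sit on the FFT grid
  tone <- cos(2 * pi * 4.7 * t)
  slow <- 0.8 + 0.2 * cos(2 * pi * 0.5 * t)
  sp <- split_bands(tone, fs)
  expect_lt(sqrt(mean(sp$baseband^2)), 0.01)
  expect_equal(sp$carrier + sp$baseband, tone)
  sp2 <- split_bands(slow, fs)
  expect_lt(sqrt(mean(sp2$carrier^2)), 0.01)
  expect_error(split_bands(tone, fs, cutoff = 30), "Nyquist")
  # simulated cell pulse: baseband matches ground-truth envelope to 2% RMS
  cfg <- test_cfg()
  ph <- cell_phantom(65, 0, 10, 0.02, 0.9)
  tr <- synthesize_pulse(cfg, list(ph), seed = 1, phi0 = 0.4)
  truth <- tr$ground_truth$per_pulse[[1]]
  nb <- band_samples(cfg)
  idx <- (band_offset(cfg) + 1):(band_offset(cfg) + nb)
  interior <- idx[120:(nb - 120)]
  ib_true <- 0.25 * input_envelope(cfg) * (truth$tc_roundtrip + 1)
  got <- split_bands(tr$samples, cfg$sampling_rate)$baseband[interior]
  want <- ib_true[120:(nb - 120)]
  expect_lt(sqrt(mean((got - want)^2)) / mean(want), 0.02)
})

test_that("min/max envelope tracks amplitude", {
  fs <- 50
  t <- (0:999) / fs
  w <- ceiling(fs / 4.7) + 1
  tone <- 0.7 * cos(2 * pi * 4.7 * t)
  env <- envelope_minmax(tone, w)
  expect_true(all(env >= 0))
  expect_equal(median(env), 0.7, tolerance = 0.02)
  # amplitude step is tracked within about one window
  amp <- ifelse(t < 10, 1, 0.4)
  env2 <- envelope_minmax(amp * cos(2 * pi * 4.7 * t), w)
  expect_equal(median(env2[t < 9]), 1, tolerance = 0.05)
  expect_equal(median(env2[t > 11]), 0.4, tolerance = 0.05)
  expect_equal(envelope_minmax(numeric(100) , w), numeric(100))
  expect_error(envelope_minmax(tone, 1), "window")
})

test_that("analytic phase recovers instantaneous phase", {
  fs <- 50
  t <- (0:2047) / fs
  ph <- analytic_phase(cos(2 * pi * 4.7 * t))
  u <- unwrap_phase(ph)
  slope <- median(diff(u)) * fs      # rad/ns
  expect_equal(slope, 2 * pi * 4.7, tolerance = 1e-3)
  # known quadratic chirp around the carrier
  theta <- 2 * pi * 4.7 * t + 0.0008 * (t - 20)^2
  rec <- unwrap_phase(analytic_phase(cos(theta)))
  interior <- 100:1948
  err <- (rec - theta) - median((rec - theta)[interior])
  expect_lt(max(abs(err[interior])), 0.01 * max(abs(theta[interior])))
  # sign flip shifts the phase by pi (mod 2pi)
  p1 <- analytic_phase(cos(2 * pi * 4.7 * t))
  p2 <- analytic_phase(-cos(2 * pi * 4.7 * t))
  d <- (p2 - p1) %% (2 * pi)
  expect_equal(median(d), pi, tolerance = 1e-6)
  expect_error(analytic_phase(numeric(64)), "undefined")
})

test_that("unwrapping restores continuity and differs by 2*pi integers", {
  # random-walk phase with steps < pi is recovered exactly
  set.seed(42)
  for (rep in 1:5) {
    truth <- cumsum(runif(400, -3, 3))
    wrapped <- (truth + pi) %% (2 * pi) - pi
    rec <- unwrap_phase(wrapped)
    expect_equal(rec - rec[1], truth - truth[1], tolerance = 1e-9)
    k <- (rec - wrapped) / (2 * pi)
    expect_equal(k, round(k), tolerance = 1e-9)
  }
  # already-continuous input passes through unchanged
  smooth <- seq(0, 2, length.out = 100)
  expect_equal(unwrap_phase(smooth), smooth)
  # a consistent frozen example: ramp of slope 3 rad/sample
  expect_equal(unwrap_phase(c(0, 3, 6 - 2 * pi, 9 - 2 * pi)),
               c(0, 3, 6, 9), tolerance = 1e-12)
})

test_that("background removal cancels the fringe ramp", {
  cfg <- test_cfg()
  cal <- reference_and_empty_pulses(cfg, phi0 = 0.9)
  sp <- split_bands(cal$empty$samples, cfg$sampling_rate)
  u <- unwrap_phase(analytic_phase(sp$carrier))
  expect_equal(remove_background(u, u), rep(0, length(u)))
  expect_error(remove_background(u, u[-1]), "length")
  # a constant offset between pulses is absorbed by the median subtraction
  expect_equal(remove_background(u + 0.3, u), rep(0, length(u)))
})

test_that("full scan demodulation recovers the phantom phase to 1%", {
  cfg <- test_cfg()
  ph <- cell_phantom(65, 0, 10, 0.02)
  tr <- synthesize_pulse(cfg, list(ph), seed = 1, phi0 = 5.5)
  cal <- reference_and_empty_pulses(cfg, phi0 = 5.5)
  d <- demodulate_scan(tr$samples, cfg, cal$empty$samples,
                       cal$reference$samples)
  truth <- tr$ground_truth$per_pulse[[1]]
  it <- d$interior
  expect_lt(max(abs(d$phase[it] - truth$phase[it])), 0.01 * max(truth$phase))
})

test_that("transmittance extraction is exact and calibration-free", {
  cfg <- test_cfg()
  cal <- reference_and_empty_pulses(cfg, phi0 = 1)
  nb <- band_samples(cfg)
  idx <- (band_offset(cfg) + 1):(band_offset(cfg) + nb)
  sp_e <- split_bands(cal$empty$samples, cfg$sampling_rate)$baseband
  # no-cell identity
  tc0 <- extract_transmittance(sp_e[idx], sp_e[idx],
                               cal$reference$samples[idx])
  expect_equal(median(tc0, na.rm = TRUE), 1, tolerance = 1e-6)
  # known round-trip power factor 0.8, recovered within 1% regardless of
  # the beam split, substrate reflectance, or buffer transmittance
  for (pars in list(c(0.5, 1, 1), c(0.25, 0.8, 0.9), c(0.7, 0.6, 0.75))) {
    cfg2 <- test_cfg(beamsplit_ratio = pars[1],
                     substrate_reflectance = pars[2],
                     buffer_transmittance = pars[3])
    ph <- cell_phantom(65, 0, 12, 0, amplitude_transmittance = 0.8^0.25)
    tr <- synthesize_pulse(cfg2, list(ph), seed = 1, phi0 = 2)
    cal2 <- reference_and_empty_pulses(cfg2, phi0 = 2)
    d <- demodulate_scan(tr$samples, cfg2, cal2$empty$samples,
                         cal2$reference$samples)
    truth <- tr$ground_truth$per_pulse[[1]]
    core <- which(truth$tc_roundtrip < 0.81)  # fully inside the cell
    expect_equal(median(d$tc[core], na.rm = TRUE), 0.8, tolerance = 0.01)
  }
})
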