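# ---- internal helpers -------------------------------------------------------

# 1-D Gaussian blur with edge replication; sigma in samples
blur_profile <- function(v, sigma_px) {
  if (sigma_px <= 0) return(v)
  half <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  padded <- c(rep(v[1], half), v, rep(v[length(v)], half))
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out)[(half + 1):(half + length(v))]
}

# PSF sigma in band samples: optical_resolution is a FWHM in um
psf_sigma_px <- function(cfg) {
  pitch <- cfg$field_of_view / band_samples(cfg)
  (cfg$optical_resolution / 2.355) / pitch
}

# per-band-sample phase and single-pass field transmittance for a scan line,
# after the optical point-spread function
line_profiles <- function(cfg, phantoms, y_line, texture_rng = FALSE) {
  x <- position_grid(cfg)
  phi <- numeric(length(x))
  tfield <- rep(1, length(x))
  overlap <- FALSE
  cover <- integer(length(x))
  for (ph in phantoms) {
    th <- sphere_thickness(ph, x, y_line)
    inside <- th > 0
    if (!any(inside)) next
    cover[inside] <- cover[inside] + 1L
    phi <- phi + 2 * pi * (2 * ph$delta_n * th) / (cfg$center_wavelength * 1e-3)
    tp <- ifelse(inside, ph$amplitude_transmittance, 1)
    if (ph$texture_scale > 0 && texture_rng) {
      rough <- blur_profile(stats::rnorm(length(x)), psf_sigma_px(cfg))
      rough <- rough / max(stats::sd(rough), 1e-12)
      tp[inside] <- pmin(1, pmax(1e-3,
        tp[inside] * (1 + ph$texture_scale * rough[inside])))
    }
    tfield <- tfield * tp
  }
  if (any(cover > 1L)) overlap <- TRUE
  s <- psf_sigma_px(cfg)
  list(phase = blur_profile(phi, s),
       tfield = blur_profile(tfield, s),
       overlap = overlap)
}

# intensity of one line scan given band profiles; returns full-window samples
line_intensity <- function(cfg, phase, tfield, phi0) {
  n <- pulse_samples(cfg)
  nb <- band_samples(cfg)
  off <- band_offset(cfg)
  P <- input_envelope(cfg)
  a <- cfg$beamsplit_ratio
  R <- rep_len(cfg$substrate_reflectance, nb)
  Ts <- rep_len(cfg$buffer_transmittance, nb)
  t2 <- tfield^2                       # round-trip field factor
  Ib <- a * (1 - a) * P * R * (Ts^2 * t2^2 + 1)
  Ii <- 2 * a * (1 - a) * P * R * Ts * t2
  tns <- (seq_len(n) - 0.5) / cfg$sampling_rate
  I <- numeric(n)
  idx <- (off + 1):(off + nb)
  I[idx] <- Ib + Ii * cos(2 * pi * fringe_frequency(cfg) * tns[idx] +
                            phase + phi0)
  I
}

empty_baseband_peak <- function(cfg) {
  a <- cfg$beamsplit_ratio
  nb <- band_samples(cfg)
  max(a * (1 - a) * input_envelope(cfg) *
        rep_len(cfg$substrate_reflectance, nb) *
        (rep_len(cfg$buffer_transmittance, nb)^2 + 1))
}

new_pulse_train <- function(samples, cfg, boundaries, phi0,
                            ground_truth = NULL) {
  structure(list(
    samples = samples,
    time_step = 1 / cfg$sampling_rate,
    pulse_period = pulse_samples(cfg) / cfg$sampling_rate,
    pulse_boundaries = as.integer(boundaries),
    cfg = cfg, phi0 = phi0,
    ground_truth = ground_truth
  ), class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %d pulses x %d samples (%.2f ns period, %g GS/s)\n",
              length(x$pulse_boundaries),
              round(x$pulse_period / x$time_step),
              x$pulse_period, 1 / x$time_step))
  invisible(x)
}

# ---- exported operations ----------------------------------------------------

#' Synthesize one line-scan interferogram
#'
#' Forward model for a single photodetected pulse. Every sample of the
#' stretched band realizes
#' \deqn{I(t) = I_b(t) + I_i(t)\cos(2\pi f t + \varphi_c(x(t)) + \varphi_0),}
#' where the baseband envelope \eqn{I_b} and interference envelope \eqn{I_i}
#' follow from the Michelson arm fields: the sample-arm field is attenuated by
#' the substrate reflectance, the buffer transmittance, and the cell's field
#' transmittance (each applied per pass, twice), and the cell's double-pass
#' phase rides on the fringe carrier. The encoded phase and transmittance
#' profiles are low-pass filtered by the configured optical resolution before
#' encoding; the attached ground truth is this post-optics profile. Additive
#' Gaussian noise of `cfg$noise_sigma` (relative to the empty-frame baseband
#' peak) is applied when nonzero.
#'
#' @param cfg An [optical_config()].
#' @param phantoms_in_view List of [cell_phantom()] whose spheres intersect
#'   this scan line (may be empty).
#' @param pulse_index 1-based pulse number; sets the scan line's flow
#'   position `(pulse_index - 1) * flow_speed / repetition_rate`.
#' @param seed Integer seed for the noise draw.
#' @param phi0 Initial phase constant of the fringe, rad; drawn uniformly on
#'   \[0, 2pi) from `seed` when `NULL`.
#' @param attach_truth Attach per-sample ground-truth phase/transmittance.
#' @return A `pulse_train` with a single pulse.
#' @export
synthesize_pulse <- function(cfg, phantoms_in_view = list(), pulse_index = 1,
                             seed = 1, phi0 = NULL, attach_truth = TRUE) {
  validate_config(cfg)
  set.seed(seed)
  if (is.null(phi0)) phi0 <- stats::runif(1, 0, 2 * pi)
  dy <- flow_step(cfg)
  y_line <- (pulse_index - 1) * dy
  pr <- line_profiles(cfg, phantoms_in_view, y_line, texture_rng = TRUE)
  I <- line_intensity(cfg, pr$phase, pr$tfield, phi0)
  if (cfg$noise_sigma > 0)
    I <- I + stats::rnorm(length(I), 0,
                          cfg$noise_sigma * empty_baseband_peak(cfg))
  gt <- NULL
  if (attach_truth)
    gt <- list(per_pulse = list(list(phase = pr$phase,
                                     tc_roundtrip = pr$tfield^4,
                                     overlap = pr$overlap)),
               population = phantoms_in_view, phi0 = phi0)
  new_pulse_train(I, cfg, 1L, phi0, gt)
}

#' Flow displacement per pulse
#'
#' Distance a cell travels between consecutive line scans,
#' `flow_speed / repetition_rate`, in um.
#' @param cfg An [optical_config()].
#' @export
flow_step <- function(cfg) cfg$flow_speed / (cfg$repetition_rate * 1e6) * 1e6

#' Synthesize a pulse train for a flowing phantom population
#'
#' Concatenates [synthesize_pulse()] line scans while the population advances
#' by [flow_step()] per pulse, so a cell of diameter `d` spans about
#' `d / flow_step(cfg)` consecutive line scans. Overlapping phantoms are
#' permitted (clump fixtures) and flagged in the ground truth. The initial
#' fringe phase is drawn once per stream.
#'
#' @param cfg An [optical_config()].
#' @param population List of [cell_phantom()] (any order).
#' @param n_pulses Number of line scans; when `NULL`, enough to cover the
#'   population plus a trailing margin.
#' @param seed Integer seed (noise and `phi0`).
#' @param attach_truth Attach per-pulse ground truth (memory-heavy for long
#'   streams; the truth stores band-length vectors only for pulses a cell
#'   touches).
#' @return A `pulse_train`.
#' @export
synthesize_stream <- function(cfg, population = list(), n_pulses = NULL,
                              seed = 1, attach_truth = TRUE) {
  validate_config(cfg)
  set.seed(seed)
  phi0 <- stats::runif(1, 0, 2 * pi)
  dy <- flow_step(cfg)
  if (is.null(n_pulses)) {
    ymax <- if (length(population))
      max(vapply(population, function(p) p$center_y + p$diameter / 2, 0)) else 0
    n_pulses <- ceiling((ymax + 4) / dy)
  }
  stopifnot(n_pulses >= 1)
  ns <- pulse_samples(cfg)
  sig <- psf_sigma_px(cfg) * cfg$field_of_view / band_samples(cfg)  # um
  lo <- vapply(population, function(p) p$center_y - p$diameter / 2 - 3 * sig, 0)
  hi <- vapply(population, function(p) p$center_y + p$diameter / 2 + 3 * sig, 0)
  samples <- numeric(ns * n_pulses)
  noise_sd <- cfg$noise_sigma * empty_baseband_peak(cfg)
  truth <- if (attach_truth) vector("list", n_pulses) else NULL
  empty_I <- line_intensity(cfg, numeric(band_samples(cfg)),
                            rep(1, band_samples(cfg)), phi0)
  for (p in seq_len(n_pulses)) {
    y <- (p - 1) * dy
    act <- which(lo <= y & hi >= y)
    if (length(act)) {
      pr <- line_profiles(cfg, population[act], y, texture_rng = TRUE)
      I <- line_intensity(cfg, pr$phase, pr$tfield, phi0)
      if (attach_truth)
        truth[[p]] <- list(phase = pr$phase, tc_roundtrip = pr$tfield^4,
                           overlap = pr$overlap)
    } else {
      I <- empty_I
    }
    if (noise_sd > 0) I <- I + stats::rnorm(ns, 0, noise_sd)
    samples[((p - 1) * ns + 1):(p * ns)] <- I
  }
  gt <- list(population = population, phi0 = phi0, per_pulse = truth)
  new_pulse_train(samples, cfg, seq(1L, by = ns, length.out = n_pulses),
                  phi0, gt)
}

#' Reference-arm-only and empty-frame calibration pulses
#'
#' The two calibration recordings that transmittance extraction needs: the
#' reference-arm intensity captured with the sample arm blocked (a single arm,
#' hence no fringe), and the empty-frame interferogram recorded with no cell
#' in the field of view. Both are noise-free single pulses sharing the
#' stream's initial fringe phase.
#'
#' @param cfg An [optical_config()].
#' @param phi0 Initial fringe phase of the stream being calibrated; drawn
#'   from `seed` when `NULL` (the reference-only pulse does not depend on it).
#' @param seed Integer seed used only when `phi0` is `NULL`.
#' @return List with elements `reference` and `empty`, both `pulse_train`s.
#' @export
reference_and_empty_pulses <- function(cfg, phi0 = NULL, seed = 1) {
  validate_config(cfg)
  if (is.null(phi0)) { set.seed(seed); phi0 <- stats::runif(1, 0, 2 * pi) }
  n <- pulse_samples(cfg)
  nb <- band_samples(cfg)
  off <- band_offset(cfg)
  a <- cfg$beamsplit_ratio
  P <- input_envelope(cfg)
  R <- rep_len(cfg$substrate_reflectance, nb)
  Iref <- numeric(n)
  Iref[(off + 1):(off + nb)] <- a * (1 - a) * P * R
  empty <- line_intensity(cfg, numeric(nb), rep(1, nb), phi0)
  list(reference = new_pulse_train(Iref, cfg, 1L, phi0),
       empty = new_pulse_train(empty, cfg, 1L, phi0))
}
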