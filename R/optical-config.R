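#' Optical and electronic configuration of the time-stretch imager
#'
#' Bundles every parameter of the spectrally encoded, time-stretched Michelson
#' interferometer needed by the forward simulator and the demodulator: the
#' illumination band, the pulse repetition rate, the wavelength-to-time map
#' (total group-velocity dispersion), the interferometer arm mismatch that
#' sets the fringe carrier, the field of view that the rainbow spans, and the
#' digitizer sampling rate.
#'
#' The interference of the two time-shifted linearly chirped copies of each
#' pulse beats at the fringe (carrier) frequency
#' \deqn{f = 2 \Delta L / (\lambda_c^2 \, D'),}
#' where \eqn{\Delta L} is the arm-length mismatch and \eqn{D'} the total
#' group delay per unit bandwidth. When `arm_mismatch` is `NULL` it is
#' back-computed so the carrier lands at `fringe_frequency` (default 4.7 GHz)
#' under the configured dispersion.
#'
#' @param center_wavelength Center wavelength of the filtered band, nm.
#' @param bandwidth Optical bandwidth interrogating the cells, nm.
#' @param repetition_rate Pulse repetition rate, MHz.
#' @param field_of_view Lateral extent of the rainbow, um.
#' @param flow_speed Cell flow speed, m/s.
#' @param total_dispersion Total group delay per unit bandwidth after time
#'   stretch, ns/nm.
#' @param arm_mismatch Michelson arm-length mismatch, um, or `NULL` to derive
#'   it from `fringe_frequency`.
#' @param fringe_frequency Target fringe carrier, GHz; used only when
#'   `arm_mismatch` is `NULL`.
#' @param beamsplit_ratio Power fraction sent to the sample arm, in (0,1).
#' @param substrate_reflectance Power reflectance of the mirror/substrate,
#'   scalar or per-wavelength vector over the band, in (0,1].
#' @param buffer_transmittance Single-pass power transmittance of buffer and
#'   channel, scalar or per-wavelength vector, in (0,1].
#' @param buffer_index Refractive index of the buffer solution.
#' @param sampling_rate Digitizer rate, GS/s.
#' @param optical_resolution Lateral optical resolution (knife-edge FWHM), um.
#' @param noise_sigma Relative intensity noise: standard deviation of the
#'   additive Gaussian noise as a fraction of the empty-frame baseband peak.
#' @param envelope_edge Fraction of the band occupied by each raised-cosine
#'   edge of the flat-top input pulse envelope.
#'
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' fringe_frequency(cfg)   # 4.7 GHz by construction
#' pulse_samples(cfg)      # samples per line scan at 50 GS/s
#' @export
optical_config <- function(center_wavelength = 1591,
                           bandwidth = 20,
                           repetition_rate = 36.6,
                           field_of_view = 130,
                           flow_speed = 1.3,
                           total_dispersion = 1.2,
                           arm_mismatch = NULL,
                           fringe_frequency = 4.7,
                           beamsplit_ratio = 0.5,
                           substrate_reflectance = 1,
                           buffer_transmittance = 1,
                           buffer_index = 1.33,
                           sampling_rate = 50,
                           optical_resolution = 2.5,
                           noise_sigma = 0,
                           envelope_edge = 0.05) {
  if (is.null(arm_mismatch)) {
    # f[GHz] = 2 dL[um]*1e-6 / ((lc[nm]*1e-9)^2 * D'[s/m]) / 1e9
    arm_mismatch <- fringe_frequency * 1e9 *
      (center_wavelength * 1e-9)^2 * total_dispersion / 2 / 1e-6
  }
  cfg <- structure(list(
    center_wavelength = center_wavelength,
    bandwidth = bandwidth,
    repetition_rate = repetition_rate,
    field_of_view = field_of_view,
    flow_speed = flow_speed,
    total_dispersion = total_dispersion,
    arm_mismatch = arm_mismatch,
    beamsplit_ratio = beamsplit_ratio,
    substrate_reflectance = substrate_reflectance,
    buffer_transmittance = buffer_transmittance,
    buffer_index = buffer_index,
    sampling_rate = sampling_rate,
    optical_resolution = optical_resolution,
    noise_sigma = noise_sigma,
    envelope_edge = envelope_edge
  ), class = "optical_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$bandwidth > 0, cfg$repetition_rate > 0, cfg$sampling_rate > 0,
            cfg$field_of_view > 0, cfg$total_dispersion > 0)
  if (cfg$beamsplit_ratio <= 0 || cfg$beamsplit_ratio >= 1)
    stop("beamsplit_ratio must lie strictly in (0,1)", call. = FALSE)
  for (nm in c("substrate_reflectance", "buffer_transmittance")) {
    v <- cfg[[nm]]
    if (any(v <= 0) || any(v > 1))
      stop(nm, " must lie in (0,1]", call. = FALSE)
  }
  # the stretched band must fit inside one repetition period
  if (cfg$bandwidth * cfg$total_dispersion >= pulse_period(cfg))
    stop("stretched bandwidth exceeds the repetition period: ",
         "bandwidth * total_dispersion must be < 1/repetition_rate",
         call. = FALSE)
  # the digitizer must resolve the fringe
  if (cfg$sampling_rate <= 2 * fringe_frequency(cfg))
    stop("sampling_rate must exceed twice the fringe frequency", call. = FALSE)
  invisible(cfg)
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  band: %g nm @ %g nm (fractional %.1f%%)\n",
              x$bandwidth, x$center_wavelength, fractional_bandwidth(x)))
  cat(sprintf("  repetition: %g MHz (period %.2f ns, %d samples at %g GS/s)\n",
              x$repetition_rate, pulse_period(x), pulse_samples(x),
              x$sampling_rate))
  cat(sprintf("  stretch: %g ns/nm -> band duration %.1f ns\n",
              x$total_dispersion, x$bandwidth * x$total_dispersion))
  cat(sprintf("  fringe: %.3f GHz (arm mismatch %.0f um)\n",
              fringe_frequency(x), x$arm_mismatch))
  cat(sprintf("  field of view: %g um, flow %g m/s, resolution %g um\n",
              x$field_of_view, x$flow_speed, x$optical_resolution))
  invisible(x)
}

#' Derived timing and spectral quantities of a configuration
#'
#' Small arithmetic accessors used throughout the pipeline: the repetition
#' period, samples per line scan, realized fringe carrier, the
#' wavelength/space grids of the stretched band, and the signal-chain
#' analytics (cell transit time in a line scan and the baseband frequency
#' bound it implies).
#'
#' @param cfg An [optical_config()].
#' @return `pulse_period`: ns. `pulse_samples`, `band_samples`,
#'   `band_offset`: sample counts. `fringe_frequency`: GHz.
#'   `fractional_bandwidth`: percent.
#' @name config-derived
NULL

#' @rdname config-derived
#' @export
pulse_period <- function(cfg) 1e3 / cfg$repetition_rate

#' @rdname config-derived
#' @export
pulse_samples <- function(cfg) round(pulse_period(cfg) * cfg$sampling_rate)

#' @rdname config-derived
#' @export
band_samples <- function(cfg)
  round(cfg$bandwidth * cfg$total_dispersion * cfg$sampling_rate)

#' @rdname config-derived
#' @export
band_offset <- function(cfg) (pulse_samples(cfg) - band_samples(cfg)) %/% 2L

#' @rdname config-derived
#' @export
fringe_frequency <- function(cfg)
  2 * (cfg$arm_mismatch * 1e-6) /
    ((cfg$center_wavelength * 1e-9)^2 * cfg$total_dispersion) / 1e9

#' @rdname config-derived
#' @export
fractional_bandwidth <- function(cfg) 100 * cfg$bandwidth / cfg$center_wavelength

#' Wavelength and lateral-position grids of the stretched band
#'
#' Sample-center wavelengths (nm) and rainbow positions (um) for the
#' `band_samples(cfg)` samples of one line scan that carry the stretched
#' spectrum. The map is linear: the shortest wavelength sits at the left edge
#' of the field of view.
#'
#' @param cfg An [optical_config()].
#' @return Numeric vector of length `band_samples(cfg)`.
#' @export
wavelength_grid <- function(cfg) {
  nb <- band_samples(cfg)
  lam0 <- cfg$center_wavelength - cfg$bandwidth / 2
  lam0 + (seq_len(nb) - 0.5) * (cfg$bandwidth / nb)
}

#' @rdname wavelength_grid
#' @export
position_grid <- function(cfg) {
  lam <- wavelength_grid(cfg)
  lam0 <- cfg$center_wavelength - cfg$bandwidth / 2
  cfg$field_of_view * (lam - lam0) / cfg$bandwidth
}

#' Input pulse intensity envelope over the band
#'
#' Flat-top envelope with raised-cosine edges occupying `envelope_edge` of the
#' band on each side, evaluated at the band sample grid. Peak normalized to 1.
#'
#' @param cfg An [optical_config()].
#' @return Numeric vector of length `band_samples(cfg)`, values in \[0, 1\].
#' @export
input_envelope <- function(cfg) {
  nb <- band_samples(cfg)
  u <- (seq_len(nb) - 0.5) / nb
  e <- cfg$envelope_edge
  ifelse(u < e, 0.5 * (1 - cos(pi * u / e)),
         ifelse(u > 1 - e, 0.5 * (1 - cos(pi * (1 - u) / e)), 1))
}

#' Signal-timing analytics of the line-scan chain
#'
#' `transit_time()` is the duration of the intensity perturbation a cell of
#' diameter `d` induces within one line scan: the cell occupies `d /
#' field_of_view` of the rainbow, hence that fraction of the pulse period.
#' `baseband_bound()` is the corresponding upper bound on the baseband
#' frequency content, `1 / transit_time`.
#'
#' @param cfg An [optical_config()].
#' @param d Cell diameter, um.
#' @return `transit_time`: ns; `baseband_bound`: GHz.
#' @export
transit_time <- function(cfg, d) (d / cfg$field_of_view) * pulse_period(cfg)

#' @rdname transit_time
#' @export
baseband_bound <- function(cfg, d) 1 / transit_time(cfg, d)
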