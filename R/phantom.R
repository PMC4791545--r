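#' Spherical cell phantom
#'
#' Ground-truth object for the forward simulator: a sphere of diameter `d`
#' with uniform refractive-index contrast `delta_n` against the buffer and a
#' uniform single-pass amplitude (field) transmittance `t_c`. Cells in
#' suspension relax to spheres, so the lateral diameter doubles as the size
#' ground truth used for volume estimates downstream.
#'
#' @param center_x Position along the rainbow (lateral), um.
#' @param center_y Position along the flow direction, um.
#' @param diameter Sphere diameter, um; must be positive.
#' @param delta_n Refractive-index contrast (cell minus buffer). Negative
#'   values are admitted only to emulate debris/bubbles in tests.
#' @param amplitude_transmittance Single-pass field transmittance in (0,1].
#'   The simulator applies it twice (double pass); the round-trip *power*
#'   factor recovered by transmittance extraction is its fourth power,
#'   recorded as `tc_roundtrip`.
#' @param texture_scale Optional relative amplitude of spatial roughness
#'   multiplying the transmittance profile (scattering-like loss); 0 disables.
#' @param label Optional class tag carried through to ground truth.
#' @return An object of class `cell_phantom`.
#' @examples
#' ph <- cell_phantom(65, 20, diameter = 10, delta_n = 0.02)
#' ph$tc_roundtrip
#' @export
cell_phantom <- function(center_x, center_y, diameter, delta_n = 0.02,
                         amplitude_transmittance = 1, texture_scale = 0,
                         label = NA_character_) {
  stopifnot(diameter > 0)
  if (amplitude_transmittance <= 0 || amplitude_transmittance > 1)
    stop("amplitude_transmittance must lie in (0,1]", call. = FALSE)
  structure(list(
    center_x = center_x, center_y = center_y, diameter = diameter,
    delta_n = delta_n, amplitude_transmittance = amplitude_transmittance,
    tc_roundtrip = amplitude_transmittance^4,
    texture_scale = texture_scale, label = label
  ), class = "cell_phantom")
}

#' Axial chord of a sphere at a lateral offset
#'
#' Thickness of the spherical phantom along the optical axis at a point
#' offset laterally by `(x, y)` from anywhere; the chord is
#' \eqn{d\sqrt{1 - (2r/d)^2}} inside the disk of radius `d/2` and 0 outside.
#'
#' @param phantom A [cell_phantom()].
#' @param x,y Lateral coordinates, um (same frame as the phantom center).
#' @return Thickness in um (vectorized over `x`/`y`).
#' @export
sphere_thickness <- function(phantom, x, y = phantom$center_y) {
  r2 <- (x - phantom$center_x)^2 + (y - phantom$center_y)^2
  R2 <- (phantom$diameter / 2)^2
  ifelse(r2 < R2, phantom$diameter * sqrt(pmax(0, 1 - r2 / R2)), 0)
}

#' Phase profile a phantom imprints on one line scan
#'
#' Double-pass optical phase at rainbow position `x` for a scan line crossing
#' the phantom at flow position `y`:
#' \deqn{\varphi_c(x) = \frac{2\pi}{\lambda_c}\,\mathrm{OPD}(x), \qquad
#'   \mathrm{OPD}(x) = 2\,\Delta n\, t(x),}
#' with \eqn{t(x)} the sphere chord. The reflection geometry traverses the
#' cell twice, hence the single factor 2 in the OPD.
#'
#' @param phantom A [cell_phantom()].
#' @param cfg An [optical_config()].
#' @param x Rainbow positions, um.
#' @param y Flow position of the scan line, um.
#' @return Phase in radians, same length as `x`.
#' @export
phantom_phase_profile <- function(phantom, cfg, x, y = phantom$center_y) {
  opd <- 2 * phantom$delta_n * sphere_thickness(phantom, x, y)  # um
  2 * pi * opd / (cfg$center_wavelength * 1e-3)
}

#' Sample a two-population phantom cohort
#'
#' Draws spherical phantoms for the package's two-population demonstration:
#' class A (smaller, lower index contrast, more transparent) versus class B
#' (larger, denser, lossier). Diameters and index contrasts are normal;
#' transmittances are normal truncated to (0,1]. Cells are strung along the
#' flow axis with randomized gaps and a lead-in so that early line scans are
#' empty frames, and placed at random rainbow positions away from the field
#' edges.
#'
#' @param n_per_class Cells per class.
#' @param cfg An [optical_config()].
#' @param seed Integer seed.
#' @param diameter_mean,diameter_sd Length-2 vectors (class A, class B), um.
#' @param delta_n_mean,delta_n_sd Length-2 vectors, dimensionless.
#' @param tc_mean,tc_sd Length-2 vectors: single-pass field transmittance.
#' @param gap Range of extra spacing between consecutive cells, um.
#' @param lead_in Cell-free flow length before the first cell, um.
#' @return List of [cell_phantom()] objects in flow order, with labels
#'   `"A"`/`"B"`.
#' @export
sample_population <- function(n_per_class = 20, cfg = optical_config(),
                              seed = 1,
                              diameter_mean = c(8, 13),
                              diameter_sd = c(1, 1.5),
                              delta_n_mean = c(0.018, 0.024),
                              delta_n_sd = c(0.002, 0.002),
                              tc_mean = c(0.97, 0.92),
                              tc_sd = c(0.01, 0.01),
                              gap = c(2, 6), lead_in = 4) {
  set.seed(seed)
  cls <- sample(rep(c(1L, 2L), n_per_class))
  n <- length(cls)
  d  <- pmax(3, stats::rnorm(n, diameter_mean[cls], diameter_sd[cls]))
  dn <- pmax(1e-3, stats::rnorm(n, delta_n_mean[cls], delta_n_sd[cls]))
  tc <- pmin(1, pmax(0.5, stats::rnorm(n, tc_mean[cls], tc_sd[cls])))
  margin <- max(d) / 2 + cfg$optical_resolution + 2
  cx <- stats::runif(n, margin, cfg$field_of_view - margin)
  gaps <- stats::runif(n, gap[1], gap[2])
  edge <- numeric(n)  # leading edge of each cell along flow
  pos <- lead_in
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cy <- pos + d[i] / 2
    out[[i]] <- cell_phantom(cx[i], cy, d[i], dn[i], tc[i],
                             label = c("A", "B")[cls[i]])
    pos <- pos + d[i] + gaps[i]
    edge[i] <- pos
  }
  out
}
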