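# Feature-level synthetic cell records: the 16-feature fingerprints of two
# phantom populations drawn directly in feature space, for exercising the
# learning stage at sizes where full waveform synthesis is unnecessary.

#' Generate synthetic cell records in feature space
#'
#' Draws records whose 16 features follow the geometry of spherical cells:
#' class A is smaller, optically thinner and more transparent than class B
#' (`effect_scale = 1` reproduces the package's two-population demonstration
#' conditions; 0 collapses the classes onto one distribution for null
#' experiments). Morphological features derive from the drawn diameter with
#' multiplicative measurement noise; phase features from the drawn index
#' contrast and the sphere volume; loss features from the drawn attenuation
#' scale. Correlations within each feature family arise naturally from the
#' shared latent variables, as they do in measured data.
#'
#' @param n Total records (classes balanced).
#' @param seed Integer seed.
#' @param effect_scale Multiplier on every between-class mean difference.
#' @param diameter_mean,diameter_sd,delta_n_mean,delta_n_sd,loss_mean,loss_sd
#'   Length-2 class parameter vectors (um, dimensionless, dimensionless).
#' @param noise Relative measurement noise on derived features.
#' @return Data frame with the 16 feature columns plus `label` ("A"/"B").
#' @export
synth_cell_records <- function(n = 1000, seed = 1, effect_scale = 1,
                               diameter_mean = c(8, 13),
                               diameter_sd = c(1, 1.5),
                               delta_n_mean = c(0.018, 0.024),
                               delta_n_sd = c(0.002, 0.002),
                               loss_mean = c(0.04, 0.10),
                               loss_sd = c(0.015, 0.03),
                               noise = 0.03) {
  set.seed(seed)
  cls <- rep_len(c(1L, 2L), n)
  blend <- function(v) v[1] + effect_scale * (v - v[1])
  dm <- blend(diameter_mean); nm <- blend(delta_n_mean)
  lm <- blend(loss_mean)
  d <- pmax(3, stats::rnorm(n, dm[cls], diameter_sd[cls]))
  dn <- pmax(1e-3, stats::rnorm(n, nm[cls], delta_n_sd[cls]))
  lo <- pmax(1e-3, stats::rnorm(n, lm[cls], loss_sd[cls]))
  px <- 0.108; py <- 0.107                  # nominal pixel pitches, um
  m <- function(sd = noise) 1 + stats::rnorm(n, 0, sd)
  d_rb <- d * m(); d_fl <- d * m()
  area <- pi / 4 * d_rb * d_fl / (px * py) * m(0.01)
  perim <- pi * (d_rb + d_fl) / 2 / sqrt(px * py) * m(0.02)
  circ <- 4 * pi * area / perim^2
  major <- pmax(d_rb, d_fl) * m(0.01)
  orient <- stats::runif(n, 0, 90)
  loose <- pi / 4 * (d_rb + 5) * (d_fl + 5) / (px * py) * m(0.01)
  med_r <- 0.146 * d * m()
  V <- pi / 6 * d^3
  opd1 <- 2 * dn * V * m()
  opd2 <- opd1 * m(noise / 3)
  ri <- opd2 / (2 * pi / 6 * d_rb^3)
  thick <- 2 / 3 * d                          # mean chord of a sphere
  sc1 <- lo * m(); sc2 <- abs(sc1) + abs(stats::rnorm(n, 0, noise * lm[cls]))
  ab <- -log(pmax(1 - lo, 0.05)) / (2 * thick)
  ab1 <- ab * m(); ab2 <- abs(ab1) + abs(stats::rnorm(n, 0, noise * mean(ab)))
  out <- data.frame(d_rb, d_fl, area, perim, circ, major, orient, loose,
                    med_r, opd1, opd2, ri, ab1, ab2, sc1, sc2,
                    check.names = FALSE)
  names(out) <- biophysical_features()
  out$label <- c("A", "B")[cls]
  out
}
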