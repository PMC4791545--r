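# Shared fixtures and independent oracles built in code.

# default configuration used across tests (noise-free unless overridden)
test_cfg <- function(...) optical_config(...)

# exhaustive-search Otsu oracle: between-class variance at every candidate
# threshold of an n-bin histogram. Thresholds inside an empty-bin gap tie
# exactly, so agreement is judged on the achieved variance, not the location.
brute_force_otsu <- function(x, levels = 256, rng = range(x)) {
  br <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- hist(x, breaks = br, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  v <- rep(NA_real_, levels)
  for (k in seq_len(levels - 1)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:k] * mids[1:k]) / w0
    mu1 <- sum(p[(k + 1):levels] * mids[(k + 1):levels]) / w1
    v[k] <- w0 * w1 * (mu0 - mu1)^2
  }
  list(threshold = mids[which.max(v)], var = v, mids = mids, breaks = br,
       bin_width = diff(br[1:2]))
}

# does a threshold achieve the maximal between-class variance (tie-aware)?
otsu_is_optimal <- function(thr, oracle, tol = 1e-9) {
  k <- findInterval(thr, oracle$breaks, all.inside = TRUE)
  k <- max(1, min(k, length(oracle$var)))
  isTRUE(oracle$var[k] >= max(oracle$var, na.rm = TRUE) * (1 - tol))
}

# exact (unblurred) OPD field of spherical phantoms on a pixel grid, plus a
# matching transmittance map; returns a quant_image_pair
synthetic_image_pair <- function(phantoms, cfg = test_cfg(),
                                 nx = 260, ny = 300, blur_psf = TRUE,
                                 noise_sd = 0) {
  px <- cfg$field_of_view / nx
  py <- px
  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * py
  opd <- matrix(0, nx, ny)
  tc <- matrix(1, nx, ny)
  for (ph in phantoms) {
    th <- outer(xs, ys, function(x, y) sphere_thickness(ph, x, y))
    # adjacent cells cannot interpenetrate: combine projections by maximum
    opd <- pmax(opd, 2 * ph$delta_n * th)
    tc <- pmin(tc, ifelse(th > 0, ph$tc_roundtrip, 1))
  }
  if (blur_psf) {
    s <- (cfg$optical_resolution / 2.355) / px
    opd <- EBImage::gblur(opd, sigma = s)
    tc <- EBImage::gblur(tc, sigma = s)
  }
  if (noise_sd > 0) opd <- opd + matrix(rnorm(nx * ny, 0, noise_sd), nx)
  cfg2 <- cfg
  cfg2$field_of_view <- nx * px
  img <- quant_image_pair(opd, tc, cfg2, y_decimation = 1)
  # force isotropic pitch for geometry fixtures
  img$pixel_pitch_y <- py
  img
}

# digitized disk mask of radius r (pixels) on a square canvas
disk_mask <- function(r, pad = 6) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  m <- matrix(0L, n, n)
  m[(row(m) - c0)^2 + (col(m) - c0)^2 <= r^2] <- 1L
  m
}

# single-cell stream fixture: one phantom centered so the stream stays short
single_cell_stream <- function(d = 10, delta_n = 0.02, tc_field = 1,
                               noise_sigma = 0, seed = 1, cx = 65) {
  cfg <- test_cfg(noise_sigma = noise_sigma)
  ph <- cell_phantom(cx, d / 2 + 2, d, delta_n, tc_field)
  list(cfg = cfg, phantom = ph,
       train = synthesize_stream(cfg, list(ph), seed = seed))
}
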