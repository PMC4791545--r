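# Cell segmentation, quality control, and the 16-feature biophysical
# fingerprint measured on the co-registered OPD/loss image pair.

#' Names of the 16 biophysical features
#'
#' Morphology (9), optical phase (3), and optical loss (4) features measured
#' per cell.
#' @return Character vector of length 16.
#' @export
biophysical_features <- function() c(
  "Diameter-RB", "Diameter-FL", "Tight Area", "Perimeter", "Circularity",
  "Major Axis", "Orientation", "Loose Area", "Median Radius",
  "OPD-1", "OPD-2", "Refractive index",
  "Absorption-1", "Absorption-2", "Scattering-1", "Scattering-2")

#' @rdname biophysical_features
#' @param records A records data frame from [measure_cells()] or
#'   [synth_cell_records()].
#' @return `feature_matrix`: numeric matrix, one row per record, 16 columns.
#' @export
feature_matrix <- function(records) {
  as.matrix(records[, biophysical_features(), drop = FALSE])
}

# 8-connected labelling: EBImage::bwlabel is 4-connected; merge labels that
# touch diagonally with a union-find pass
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  m <- max(lab)
  if (m < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  d1 <- cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1]))
  d2 <- cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))
  prs <- rbind(d1, d2)
  prs <- prs[prs[, 1] > 0 & prs[, 2] > 0 & prs[, 1] != prs[, 2], ,
             drop = FALSE]
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(prs)) for (k in seq_len(nrow(prs))) {
    a <- find(prs[k, 1]); b <- find(prs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(m), find, 0L)
  new_id <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- new_id[lab[lab > 0]]
  out
}

#' Segment cells in the OPD image
#'
#' Smooths the image with a Gaussian whose sigma matches the optical
#' resolution (`optical_resolution / 2.355`, i.e. the PSF standard
#' deviation), removing artifacts below the resolution limit, then binarizes
#' at Otsu's between-class-variance-maximizing threshold (256-bin histogram
#' of the smoothed image) and labels connected components
#' (8-connectivity). A blank (flat) image yields an empty label set.
#'
#' @param images A `quant_image_pair` (segmentation runs on the OPD channel).
#' @param levels Histogram bins for the Otsu threshold.
#' @return List with `labels` (integer matrix), `smoothed`, `threshold`, and
#'   `n_objects`.
#' @export
segment_cells <- function(images, levels = 256) {
  sm <- EBImage::gblur(images$opd,
                       sigma = (images$cfg$optical_resolution / 2.355) /
                         images$pixel_pitch_x)
  rng <- range(sm)
  if (diff(rng) < .Machine$double.eps^0.5)
    return(list(labels = matrix(0L, nrow(sm), ncol(sm)), smoothed = sm,
                threshold = NA_real_, n_objects = 0L))
  thr <- EBImage::otsu(EBImage::Image(sm), range = rng, levels = levels)
  lab <- label8(sm > thr)
  list(labels = lab, smoothed = sm, threshold = thr,
       n_objects = max(lab))
}

#' Split clumped cells at intensity saddle points
#'
#' Object centers are local intensity maxima of the smoothed image; objects
#' containing two or more well-separated maxima (saddle depth exceeding
#' `tolerance_frac` of the image maximum) are split along the watershed line
#' between them. The output object count is never smaller than the input
#' count; single convex objects pass unchanged.
#'
#' @param seg Result of [segment_cells()].
#' @param tolerance_frac Minimum saddle depth between maxima, as a fraction
#'   of the smoothed-image maximum, for a split.
#' @return `seg` with `labels` and `n_objects` refined.
#' @export
declump <- function(seg, tolerance_frac = 0.1) {
  if (seg$n_objects == 0) return(seg)
  tol <- tolerance_frac * max(seg$smoothed)
  ws <- EBImage::watershed(EBImage::Image(seg$smoothed * (seg$labels > 0)),
                           tolerance = tol, ext = 1)
  lab <- array(as.integer(ws), dim = dim(seg$labels))
  seg$labels <- lab
  seg$n_objects <- max(lab)
  seg
}

#' Discard border objects and debris
#'
#' Removes objects touching the image borders (edges of the field of view or
#' of the acquisition window) and flags as debris objects that are too small
#' (equivalent diameter below `min_diameter`) or too elongated (aspect ratio
#' above `max_aspect`).
#'
#' @param seg Segmentation (with `labels`) from [segment_cells()]/[declump()].
#' @param images The `quant_image_pair` (for pixel pitches).
#' @param min_diameter Minimum equivalent diameter, um.
#' @param max_aspect Maximum major/minor axis ratio.
#' @return `seg` with filtered `labels`, plus a `flags` data frame
#'   (object id, flag in `none`/`border`/`debris`, retained).
#' @export
qc_filter <- function(seg, images, min_diameter = 3, max_aspect = 5) {
  lab <- seg$labels
  m <- max(lab)
  if (m == 0) {
    seg$flags <- data.frame(id = integer(), flag = character(),
                            retained = logical())
    return(seg)
  }
  px <- images$pixel_pitch_x; py <- images$pixel_pitch_y
  nr <- nrow(lab); nc <- ncol(lab)
  flags <- character(m)
  for (id in seq_len(m)) {
    pix <- which(lab == id, arr.ind = TRUE)
    if (!nrow(pix)) { flags[id] <- "debris"; next }
    if (any(pix[, 1] == 1L | pix[, 1] == nr |
            pix[, 2] == 1L | pix[, 2] == nc)) {
      flags[id] <- "border"; next
    }
    area_um2 <- nrow(pix) * px * py
    eqd <- 2 * sqrt(area_um2 / pi)
    mom <- shape_moments(pix, px, py)
    if (eqd < min_diameter || mom$aspect > max_aspect) {
      flags[id] <- "debris"; next
    }
    flags[id] <- "none"
  }
  keep <- which(flags == "none")
  out <- array(0L, dim = dim(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  seg$labels <- out
  seg$n_objects <- length(keep)
  seg$flags <- data.frame(id = seq_len(m), flag = flags,
                          retained = flags == "none")
  seg
}

# second-central-moment ellipse of a pixel set, in um; the 1/12 terms are the
# variance of a unit pixel, which keeps 1-pixel-wide objects non-degenerate
shape_moments <- function(pix, px, py) {
  xs <- pix[, 1] * px; ys <- pix[, 2] * py
  cxx <- stats::var(xs) * (length(xs) - 1) / length(xs) + px^2 / 12
  cyy <- stats::var(ys) * (length(ys) - 1) / length(ys) + py^2 / 12
  cxy <- if (length(xs) > 1)
    stats::cov(xs, ys) * (length(xs) - 1) / length(xs) else 0
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)
  major <- 4 * sqrt(ev$values[1])
  minor <- 4 * sqrt(max(ev$values[2], .Machine$double.eps))
  v <- ev$vectors[, 1]
  # angle between the major axis and the flow direction (the y/column axis)
  orient <- acos(min(1, abs(v[2]))) * 180 / pi
  list(major = major, minor = minor, aspect = major / minor,
       orientation = orient,
       centroid = c(mean(xs) - px / 2, mean(ys) - py / 2))
}

#' Expand a tight mask into a loose measurement boundary
#'
#' Morphological dilation by a disk of physical radius `radius` (default the
#' optical resolution, 2.5 um): the point-spread function smears cell signal
#' beyond the segmented boundary, so pixel intensities are measured and
#' integrated within this expanded region.
#'
#' @param mask Logical/0-1 matrix (tight mask).
#' @param pitch Pixel pitch, um (scalar; use the mean of anisotropic
#'   pitches).
#' @param radius Expansion radius, um; 0 returns the mask unchanged.
#' @return Logical matrix, a superset of `mask`.
#' @export
expand_boundary <- function(mask, pitch, radius = 2.5) {
  if (radius <= 0 || !any(mask > 0)) return(mask > 0)
  r_px <- max(1L, round(radius / pitch))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  EBImage::dilate(mask > 0, brush) > 0
}

#' Sphere-plus-PSF fit of diameter and index contrast
#'
#' The OPD image of a spherical cell observed through a Gaussian point-spread
#' function keeps its integral (`2 dn V`) but its peak is attenuated by a
#' computable factor `beta(d, sigma)` (the chord profile convolved with the
#' PSF, evaluated at the center). Given the measured integral `I` and peak
#' `p`, the diameter solves `pi d^2 / (6 beta(d)) = I / p` and the contrast
#' follows as `dn = p / (2 d beta(d))`. This removes the diameter-cubed bias
#' that a thresholded extent would propagate into the volume.
#'
#' @param integral Integrated OPD over the cell, um^3.
#' @param peak Peak OPD, um.
#' @param sigma PSF standard deviation, um (`optical_resolution / 2.355`).
#' @return List with `diameter` (um) and `delta_n`.
#' @export
sphere_fit_opd <- function(integral, peak, sigma) {
  if (integral <= 0 || peak <= 0)
    return(list(diameter = NA_real_, delta_n = NA_real_))
  beta <- function(d) {
    # central value of the 2-D Gaussian-blurred chord, relative to d
    r <- seq(0, d / 2, length.out = 200)
    chord <- sqrt(pmax(0, 1 - (2 * r / d)^2))
    w <- exp(-r^2 / (2 * sigma^2)) / sigma^2 * r
    sum(chord * w) * (r[2] - r[1])
  }
  g <- function(d) pi * d^2 / (6 * beta(d)) - integral / peak
  if (g(0.5) > 0) return(list(diameter = 0.5, delta_n = peak))
  d <- stats::uniroot(g, c(0.5, 100), tol = 1e-4)$root
  list(diameter = d, delta_n = peak / (2 * d * beta(d)))
}

# perimeter estimate: boundary chain-code length with Kulpa weights plus a
# half-pixel boundary offset (2*pi*0.5); converges to the true perimeter for
# digitized disks
chain_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2) return(pi)
  d <- contour - contour[c(2:n, 1), ]
  0.9481 * sum(sqrt(rowSums(d^2))) + pi
}

#' Measure the 16 biophysical features of every retained cell
#'
#' For each labeled object: diameters along the rainbow and the flow
#' (bounding extents, calibrated for the thresholding geometry -- an Otsu cut
#' at fraction `h` of a spherical phase profile's peak crosses it at extent
#' `d * sqrt(1 - h^2)`, which is divided out); tight/loose areas and the
#' chain-code perimeter; circularity `4 pi A / P^2`; the
#' normalized-second-central-moment ellipse's major axis and its orientation
#' to the flow axis; the median distance of object pixels to the exterior;
#' integrated OPD over the loose boundary, raw (`OPD-1`) and additionally
#' calibrated by the pulse-to-pulse line gain over a 1 us window (`OPD-2`);
#' the mean refractive-index contrast from the sphere-plus-PSF fit of
#' [sphere_fit_opd()] on the calibrated OPD integral and peak (a proxy for
#' protein concentration); and the optical-loss features under an
#' absorption-dominant model
#' (per-pixel attenuation coefficient `-log(T_c)/(2 t)` with `t` the
#' OPD-implied thickness; mean and mean-absolute) and a scattering-dominant
#' model (per-pixel loss `1 - T_c`; mean and mean-absolute).
#'
#' @param seg Filtered segmentation from [qc_filter()].
#' @param images The `quant_image_pair`.
#' @param expand_radius Loose-boundary radius, um (default: the configured
#'   optical resolution).
#' @param min_thickness Minimum OPD-implied thickness (um) for a pixel to
#'   enter the absorption average.
#' @return Data frame: 16 feature columns (names from
#'   [biophysical_features()]) plus `.id`, `.cx`, `.cy` (centroid, um).
#'   Degenerate objects are dropped.
#' @export
measure_cells <- function(seg, images, expand_radius = NULL,
                          min_thickness = 0.5) {
  if (is.null(expand_radius)) expand_radius <- images$cfg$optical_resolution
  lab <- seg$labels
  m <- max(lab)
  px <- images$pixel_pitch_x; py <- images$pixel_pitch_y
  dA <- px * py
  gain_row <- images$line_gain
  contours <- if (m > 0) EBImage::ocontour(lab) else list()
  rows <- vector("list", m)
  for (id in seq_len(m)) {
    pix <- which(lab == id, arr.ind = TRUE)
    if (nrow(pix) < 2) next
    mom <- shape_moments(pix, px, py)
    perim <- chain_perimeter(contours[[id]])
    if (perim <= 0) next
    h <- min(seg$threshold / max(seg$smoothed[pix]), 0.95)
    cal <- 1 / sqrt(1 - h^2)
    d_rb <- (diff(range(pix[, 1])) + 1) * px * cal
    d_fl <- (diff(range(pix[, 2])) + 1) * py * cal
    # cropped loose mask
    rpx <- ceiling(expand_radius / min(px, py)) + 2L
    r0 <- max(1L, min(pix[, 1]) - rpx); r1 <- min(nrow(lab), max(pix[, 1]) + rpx)
    c0 <- max(1L, min(pix[, 2]) - rpx); c1 <- min(ncol(lab), max(pix[, 2]) + rpx)
    tight_crop <- lab[r0:r1, c0:c1] == id
    loose_crop <- expand_boundary(tight_crop, mean(c(px, py)), expand_radius)
    dm <- EBImage::distmap(tight_crop)
    med_r <- stats::median(dm[tight_crop]) * mean(c(px, py))
    opd_crop <- images$opd[r0:r1, c0:c1]
    tc_crop <- images$tc[r0:r1, c0:c1]
    gain_crop <- matrix(gain_row[c0:c1], nrow = nrow(tight_crop),
                        ncol = c1 - c0 + 1L, byrow = TRUE)
    opd1 <- sum(opd_crop[loose_crop]) * dA
    opd_gc <- opd_crop / gain_crop
    opd2 <- sum(opd_gc[loose_crop]) * dA
    peak <- stats::quantile(opd_gc[loose_crop], 0.999, names = FALSE)
    fit <- sphere_fit_opd(opd2, peak,
                          images$cfg$optical_resolution / 2.355)
    ri <- if (is.finite(fit$delta_n)) fit$delta_n else
      opd2 / (2 * pi / 6 * d_rb^3)
    tc_gc <- tc_crop / gain_crop
    l_gc <- 1 - tc_gc
    thick <- pmax(opd_gc, 0) / (2 * max(ri, 1e-4))
    ab_ok <- loose_crop & thick >= min_thickness
    alpha <- -log(pmax(tc_gc, 1e-6)) / (2 * pmax(thick, min_thickness))
    rows[[id]] <- data.frame(
      `Diameter-RB` = d_rb, `Diameter-FL` = d_fl,
      `Tight Area` = nrow(pix), `Perimeter` = perim,
      `Circularity` = 4 * pi * nrow(pix) / perim^2,
      `Major Axis` = mom$major, `Orientation` = mom$orientation,
      `Loose Area` = sum(loose_crop), `Median Radius` = med_r,
      `OPD-1` = opd1, `OPD-2` = opd2, `Refractive index` = ri,
      `Absorption-1` = if (any(ab_ok)) mean(alpha[ab_ok]) else 0,
      `Absorption-2` = if (any(ab_ok)) mean(abs(alpha[ab_ok])) else 0,
      `Scattering-1` = mean(l_gc[loose_crop]),
      `Scattering-2` = mean(abs(l_gc[loose_crop])),
      .id = id,
      .cx = mom$centroid[1], .cy = mom$centroid[2],
      check.names = FALSE)
  }
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Clean a records table
#'
#' Two-pass cleaning: records with negative integrated phase (`OPD-1` < 0)
#' are removed first as debris (air bubbles, flow turbulence, recognition
#' errors); then Hotelling's T-squared is computed on the standardized
#' 16-feature matrix (pooled over classes) and the top 2% most extreme
#' records (ceiling count) are removed as outliers. With fewer than
#' `min_records` rows the outlier pass is skipped with a warning. A singular
#' covariance is ridge-regularized (`1e-6` of the mean diagonal) with a
#' warning.
#'
#' @param records Records data frame.
#' @param outlier_frac Fraction removed by the T-squared pass.
#' @param min_records Minimum rows for the outlier pass.
#' @return The filtered data frame; attribute `removed` holds a data frame
#'   of dropped row indices and reasons.
#' @export
clean_records <- function(records, outlier_frac = 0.02, min_records = 50) {
  neg <- which(records[["OPD-1"]] < 0)
  removed <- data.frame(row = neg,
                        reason = rep("negative_phase", length(neg)))
  kept <- if (length(neg)) records[-neg, , drop = FALSE] else records
  n <- nrow(kept)
  if (n < min_records) {
    warning("fewer than ", min_records,
            " records; skipping T-squared outlier removal")
  } else {
    x <- scale(feature_matrix(kept))
    x[!is.finite(x)] <- 0
    S <- stats::cov(x)
    if (kappa(S) > 1e10 || inherits(try(solve(S), silent = TRUE),
                                    "try-error")) {
      warning("singular feature covariance; ridge-regularizing")
      S <- S + diag(1e-6 * mean(diag(S)), ncol(S))
    }
    t2 <- stats::mahalanobis(x, colMeans(x), S)
    k <- ceiling(outlier_frac * n)
    drop <- order(t2, decreasing = TRUE)[seq_len(k)]
    orig <- setdiff(seq_len(nrow(records)), neg)
    removed <- rbind(removed,
                     data.frame(row = orig[drop],
                                reason = rep("t2_outlier", k)))
    kept <- kept[-drop, , drop = FALSE]
  }
  attr(kept, "removed") <- removed
  kept
}

#' Pairwise feature correlation matrix
#'
#' Pearson correlations among the 16 features; symmetric with unit diagonal.
#' Zero-variance features yield masked (`NA`) off-diagonal entries with a
#' warning.
#'
#' @param records Records data frame (at least 3 rows).
#' @return 16 x 16 correlation matrix.
#' @export
feature_correlation <- function(records) {
  if (nrow(records) < 3) stop("need at least 3 records", call. = FALSE)
  x <- feature_matrix(records)
  sds <- apply(x, 2, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  if (any(sds == 0)) {
    warning("zero-variance feature(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "),
            "; masking correlations")
    r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  }
  diag(r) <- 1
  r
}

#' Rank features by single-feature classification AUC
#'
#' For each feature, the AUC of using the raw feature value as the score,
#' oriented so AUC >= 0.5, sorted in descending order.
#'
#' @param records Records data frame or 16-column feature matrix.
#' @param labels Two-level class vector aligned with rows.
#' @return Data frame with `feature` and `auc`, best first.
#' @export
single_feature_auc <- function(records, labels) {
  x <- if (is.data.frame(records)) feature_matrix(records) else records
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) != 2) stop("need exactly two classes", call. = FALSE)
  auc <- apply(x, 2, function(v) max(auc_rank(v, y), 1 - auc_rank(v, y)))
  out <- data.frame(feature = colnames(x), auc = auc, row.names = NULL)
  out[order(-out$auc), ]
}
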