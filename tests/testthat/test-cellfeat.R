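# Segmentation, declumping, QC, the 16 features, cleaning, correlation,
# single-feature AUC.

test_that("Otsu segmentation matches the brute-force variance argmax", {
  set.seed(1)
  # bimodal toy image
  img_vals <- c(rnorm(1000, 0.1, 0.02), rnorm(200, 0.6, 0.05))
  toy <- quant_image_pair(matrix(img_vals, 40), cfg = test_cfg(),
                          y_decimation = 1)
  thr_pkg <- EBImage::otsu(EBImage::Image(toy$opd), range = range(toy$opd))
  oracle <- brute_force_otsu(as.numeric(toy$opd))
  expect_true(otsu_is_optimal(thr_pkg, oracle))
  # the threshold separates the two modes
  expect_gt(thr_pkg, 0.2); expect_lt(thr_pkg, 0.5)
  # a realistic sphere image
  ph <- cell_phantom(60, 15, 10, 0.02)
  img <- synthetic_image_pair(list(ph), noise_sd = 0.003)
  seg <- segment_cells(img)
  oracle2 <- brute_force_otsu(as.numeric(seg$smoothed))
  expect_true(otsu_is_optimal(seg$threshold, oracle2))
})

test_that("blank images give an empty label set", {
  img <- quant_image_pair(matrix(0.5, 60, 60), cfg = test_cfg(),
                          y_decimation = 1)
  seg <- segment_cells(img)
  expect_equal(seg$n_objects, 0)
})

test_that("a simulated phantom segments to its true size", {
  ph <- cell_phantom(60, 15, 10, 0.02)
  img <- synthetic_image_pair(list(ph), noise_sd = 0.003)
  seg <- segment_cells(img)
  expect_equal(seg$n_objects, 1)
  area <- sum(seg$labels == 1) * img$pixel_pitch_x * img$pixel_pitch_y
  eqd <- 2 * sqrt(area / pi)
  expect_lt(abs(eqd - 10), 2.5)
})

test_that("declumping splits touching cells and leaves singles alone", {
  cfg <- test_cfg()
  two <- list(cell_phantom(55, 12, 10, 0.02),
              cell_phantom(61, 17.3, 10, 0.02))   # centers 8 um apart
  img2 <- synthetic_image_pair(two, cfg)
  seg2 <- declump(segment_cells(img2))
  expect_equal(seg2$n_objects, 2)
  one <- synthetic_image_pair(list(cell_phantom(60, 15, 10, 0.02)), cfg)
  seg1 <- segment_cells(one)
  expect_equal(declump(seg1)$n_objects, seg1$n_objects)
  chain <- list(cell_phantom(48, 12, 10, 0.02),
                cell_phantom(56, 17.5, 10, 0.02),
                cell_phantom(64, 23, 10, 0.02))
  img3 <- synthetic_image_pair(chain, cfg, ny = 360)
  seg3 <- declump(segment_cells(img3))
  expect_equal(seg3$n_objects, 3)
})

test_that("QC removes border objects and debris", {
  cfg <- test_cfg()
  border_ph <- cell_phantom(2, 15, 10, 0.02)      # overlaps row 1
  good <- cell_phantom(60, 24, 10, 0.02)
  img <- synthetic_image_pair(list(border_ph, good), cfg)
  seg <- qc_filter(declump(segment_cells(img)), img)
  expect_equal(seg$n_objects, 1)
  expect_true("border" %in% seg$flags$flag)
  rec <- measure_cells(seg, img)
  expect_equal(nrow(rec), 1)
  expect_lt(abs(rec$`Diameter-RB` - 10), 2.5)
  # debris rules on hand-built labels: a 1.5 um speck and a 5:1 streak
  lab <- matrix(0L, 80, 80)
  lab[40:60, 10:30] <- 1L            # ~10 um cell at 0.5 um pitch
  lab[10:12, 60:62] <- 2L            # 1.5 um speck
  lab[70:71, 10:60] <- 3L            # 1 x 25 um streak
  seg2 <- list(labels = lab, smoothed = matrix(1, 80, 80), threshold = 0.5,
               n_objects = 3L)
  img2 <- quant_image_pair(matrix(0, 80, 80), cfg = cfg, y_decimation = 1)
  img2$pixel_pitch_x <- img2$pixel_pitch_y <- 0.5
  out <- qc_filter(seg2, img2)
  expect_equal(out$n_objects, 1)
  expect_equal(out$flags$flag, c("none", "debris", "debris"))
})

test_that("boundary expansion dilates by the physical radius", {
  m <- disk_mask(26, pad = 45)                    # r = 5 um at 0.19 um pitch
  loose <- expand_boundary(m, pitch = 0.19231, radius = 2.5)
  expect_equal(sum(loose) / sum(m), (7.5 / 5)^2, tolerance = 0.03)
  expect_true(all(loose[m > 0]))
  expect_equal(expand_boundary(m, 0.19, 0), m > 0)
  empty <- matrix(0L, 10, 10)
  expect_equal(sum(expand_boundary(empty, 0.19, 2.5)), 0)
})

test_that("circularity of digitized disks approaches one", {
  cfg <- test_cfg()
  for (r_um in c(4.5, 6)) {
    ph <- cell_phantom(60, 15, 2 * r_um, 0.02)
    img <- synthetic_image_pair(list(ph), cfg)
    seg <- qc_filter(segment_cells(img), img)
    rec <- measure_cells(seg, img)
    expect_lt(abs(rec$Circularity - 1), 0.08)
    expect_lte(rec$Circularity, 1 + 4 / rec$Perimeter)
    expect_gte(rec$`Loose Area`, rec$`Tight Area`)
  }
})

test_that("features recover phantom ground truth on a small population", {
  cfg <- test_cfg(noise_sigma = 0.01)
  set.seed(11)
  ds <- c(9.5, 11, 12.5, 14)
  dns <- c(0.018, 0.022, 0.02, 0.024)
  phs <- lapply(seq_along(ds), function(i)
    cell_phantom(30 + 20 * i, 15 + 32 * (i - 1), ds[i], dns[i], 0.95))
  img <- synthetic_image_pair(phs, cfg, ny = 1100, noise_sd = 0.003)
  seg <- qc_filter(declump(segment_cells(img)), img)
  rec <- measure_cells(seg, img)
  expect_equal(nrow(rec), 4)
  rec <- rec[order(rec$.cy), ]
  expect_lt(mean(abs(rec$`Diameter-RB` - ds)), 2.5)
  expect_lt(abs(mean(rec$`Refractive index`) - mean(dns)) / mean(dns), 0.05)
  expect_true(all(rec$`Loose Area` >= rec$`Tight Area`))
  expect_true(all(rec$Circularity <= 1 + 4 / rec$Perimeter))
})

test_that("cleaning removes negative-phase debris then exactly 2% by T2", {
  rec <- synth_cell_records(1000, seed = 3)
  cleaned <- clean_records(rec)
  expect_equal(nrow(cleaned), 1000 - 20)
  expect_equal(sum(attr(cleaned, "removed")$reason == "t2_outlier"), 20)
  # planted negative-phase record goes first, and a 10-sigma outlier is
  # always in the removed set (Mahalanobis oracle)
  rec2 <- rec
  rec2[["OPD-1"]][5] <- -1
  x <- feature_matrix(rec)
  mu <- colMeans(x); sdv <- apply(x, 2, sd)
  rec2[17, biophysical_features()] <- mu + 10 * sdv
  cleaned2 <- clean_records(rec2)
  removed <- attr(cleaned2, "removed")
  expect_true(5 %in% removed$row[removed$reason == "negative_phase"])
  expect_true(17 %in% removed$row[removed$reason == "t2_outlier"])
  # small tables skip the outlier pass with a warning
  expect_warning(small <- clean_records(rec[1:30, ]), "skipping")
  expect_equal(nrow(small), 30)
})

test_that("feature correlations are symmetric with unit diagonal", {
  rec <- synth_cell_records(400, seed = 7)
  r <- feature_correlation(rec)
  expect_equal(dim(r), c(16, 16))
  expect_equal(diag(r), rep(1, 16), ignore_attr = TRUE)
  expect_equal(r, t(r))
  # duplicated features correlate perfectly
  rec2 <- rec
  rec2[["Diameter-FL"]] <- rec2[["Diameter-RB"]]
  expect_equal(feature_correlation(rec2)["Diameter-RB", "Diameter-FL"], 1)
  # zero-variance features are masked with a warning
  rec3 <- rec
  rec3[["Orientation"]] <- 1
  expect_warning(r3 <- feature_correlation(rec3), "zero-variance")
  expect_true(all(is.na(r3["Orientation", -which(colnames(r3) ==
                                                   "Orientation")])))
  # independent features decorrelate at large n
  set.seed(1)
  ind <- as.data.frame(matrix(rnorm(10000 * 16), ncol = 16))
  names(ind) <- biophysical_features()
  r4 <- feature_correlation(ind)
  expect_lt(max(abs(r4[upper.tri(r4)])), 0.05)
})

test_that("single-feature AUC ranking matches closed forms", {
  set.seed(2)
  n <- 10000
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 16), ncol = 16)
  colnames(x) <- biophysical_features()
  x[, 1] <- y + 0.0001 * rnorm(n)              # carries the label
  x[, 2] <- rnorm(n, mean = ifelse(y == 1, 1, -1))  # d' = 2
  out <- single_feature_auc(x, y)
  expect_equal(out$feature[1], "Diameter-RB")
  expect_equal(out$auc[out$feature == "Diameter-RB"], 1)
  expect_equal(out$auc[out$feature == "Diameter-FL"], pnorm(2 / sqrt(2)),
               tolerance = 0.01)
  others <- out$auc[!out$feature %in% c("Diameter-RB", "Diameter-FL")]
  expect_lt(max(others), 0.52)
  expect_error(single_feature_auc(x, rep(0, n)), "two classes")
})
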