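# Orchestration: configuration files, artifact I/O, seeding, stage logging,
# and the end-to-end two-population demonstration.

#' Read a run configuration file
#'
#' Plain-text YAML with sections `optics`, `phantoms`, `pipeline`,
#' `learning`; every key under `optics` is passed to [optical_config()].
#' Missing sections fall back to package defaults.
#'
#' @param path YAML file path.
#' @return List with `cfg` (an [optical_config()]) and the raw sections.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(optical_config, raw$optics %||% list())
  list(cfg = cfg, phantoms = raw$phantoms %||% list(),
       pipeline = raw$pipeline %||% list(),
       learning = raw$learning %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pulse-train and feature-table artifact I/O
#'
#' Pulse trains are stored as RDS (samples, boundaries, configuration and
#' optional ground truth); feature tables as CSV with the canonical feature
#' names preserved.
#'
#' @param train A `pulse_train`.
#' @param path Output path.
#' @return The path, invisibly (`read_*` return the object).
#' @export
write_pulse_train <- function(train, path) {
  saveRDS(train, path)
  invisible(path)
}

#' @rdname write_pulse_train
#' @export
read_pulse_train <- function(path) readRDS(path)

#' @rdname write_pulse_train
#' @param records Records data frame.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pulse_train
#' @export
read_records_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Manifest of a pipeline run
#'
#' Records the configuration snapshot, per-stage seeds, package version and
#' MD5 checksums of the artifact files, so identical inputs can be verified
#' to reproduce identical outputs.
#'
#' @param cfg The [optical_config()] used.
#' @param seeds Named list/vector of per-stage seeds.
#' @param files Character vector of artifact paths.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(cfg, seeds, files = character()) {
  sums <- if (length(files)) tools::md5sum(files) else character()
  structure(list(config = unclass(cfg), seeds = seeds,
                 version = as.character(utils::packageVersion("tsqpi")),
                 checksums = sums, timestamp = format(Sys.time())),
            class = "run_manifest")
}

#' End-to-end two-population demonstration
#'
#' Runs the full chain on synthetic data: sample two phantom populations
#' (class A: d ~ N(8, 1) um, dn ~ N(0.018, 0.002), more transparent;
#' class B: d ~ N(13, 1.5) um, dn ~ N(0.024, 0.002), lossier), synthesize
#' the interferogram stream, reconstruct the OPD/loss image pair, segment,
#' QC-filter and measure the 16 features, clean the table, rank
#' single-feature AUCs, cross-validate the GA-trained AUC network, benchmark
#' the conventional classifiers on the same folds, and project onto the
#' first two principal components. Labels are recovered by matching each
#' record's flow-position centroid to the nearest ground-truth phantom.
#'
#' @param seed Integer seed driving every stage.
#' @param n_per_class Cells per class.
#' @param cfg An [optical_config()]; the default adds 1% relative intensity
#'   noise.
#' @param control A [ga_control()]; the default is scaled to the
#'   demonstration's record count.
#' @param k Cross-validation folds.
#' @param methods Baseline methods to benchmark.
#' @return List of class `tsqpi_demo`: cleaned `records` with labels,
#'   `single_feature` ranking, `cv` (AUC-network cross-validation), `bench`
#'   (baselines), `pca`, `multivariate_auc`, `best_single_auc` (mean
#'   per-fold test AUC of the top-ranked single feature), and `counts`
#'   (records surviving each stage).
#' @export
demo_two_populations <- function(seed = 1, n_per_class = 20,
                                 cfg = optical_config(noise_sigma = 0.01),
                                 control = ga_control(population = 30,
                                                      generations = 30,
                                                      patience = 10),
                                 k = 5,
                                 methods = c("svm", "lr", "nb", "dnn")) {
  pop <- sample_population(n_per_class, cfg, seed = seed)
  train <- synthesize_stream(cfg, pop, seed = seed + 1,
                             attach_truth = FALSE)
  img <- reconstruct_images(train)
  seg <- qc_filter(declump(segment_cells(img)), img)
  rec <- measure_cells(seg, img)
  if (is.null(rec) || nrow(rec) < 2 * k)
    stop("segmentation stage yielded too few cells", call. = FALSE)
  # label by nearest ground-truth phantom along the flow axis
  cy <- vapply(pop, function(p) p$center_y, 0)
  lab <- vapply(pop, function(p) p$label, "")
  nearest <- vapply(rec$.cy, function(y) which.min(abs(cy - y)), 0L)
  ok <- abs(cy[nearest] - rec$.cy) <
    vapply(pop, function(p) p$diameter, 0)[nearest] / 2 + 2
  rec <- rec[ok, , drop = FALSE]
  rec$label <- lab[nearest[ok]]
  counts <- c(segmented = seg$n_objects + sum(!seg$flags$retained),
              qc_retained = seg$n_objects, measured = nrow(rec))
  cleaned <- suppressWarnings(clean_records(rec))
  counts["cleaned"] <- nrow(cleaned)
  x <- feature_matrix(cleaned)
  y <- cleaned$label
  sfa <- single_feature_auc(cleaned, y)
  cv <- crossval(x, y, k = k, control = control, seed = seed)
  bench <- baselines(x, y, cv$fold_id, methods = methods, seed = seed)
  pca <- pca_view(cleaned)
  best_feat <- sfa$feature[1]
  per_fold_best <- vapply(seq_len(k), function(f) {
    te <- which(cv$fold_id == f)
    v <- x[, best_feat]
    # orient the feature on the training portion
    up <- auc_rank(v[-te], y[-te]) >= 0.5
    auc_rank(if (up) v[te] else -v[te], y[te])
  }, 0)
  structure(list(records = cleaned, single_feature = sfa, cv = cv,
                 bench = bench, pca = pca,
                 multivariate_auc = cv$mean_auc,
                 best_single_auc = mean(per_fold_best),
                 best_single_feature = best_feat,
                 counts = counts, seed = seed),
            class = "tsqpi_demo")
}

#' @export
print.tsqpi_demo <- function(x, ...) {
  cat("<tsqpi_demo>\n")
  cat("  records surviving stages: ",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  multivariate test AUC: %.3f (balanced accuracy %.1f%%)\n",
              x$multivariate_auc, x$cv$mean_balanced_accuracy))
  cat(sprintf("  best single feature: %s (test AUC %.3f)\n",
              x$best_single_feature, x$best_single_auc))
  cat("  baseline balanced accuracies (median):\n")
  s <- x$bench$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %-4s %.1f%%\n", s$method[i], s$median_ba[i]))
  invisible(x)
}
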