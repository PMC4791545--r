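# Conventional classifiers evaluated on the same folds as the AUC network,
# learning curves, and the PCA view of the feature space.

fit_baseline <- function(method, x_tr, y_tr) {
  df <- data.frame(x_tr)
  df$y <- factor(y_tr)
  switch(method,
    svm = {
      fit <- e1071::svm(y ~ ., data = df, kernel = "radial",
                        probability = TRUE, scale = TRUE)
      function(newx) {
        p <- predict(fit, data.frame(newx), probability = TRUE)
        attr(p, "probabilities")[, "1"]
      }
    },
    lr = {
      fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
      function(newx)
        suppressWarnings(as.numeric(predict(fit, data.frame(newx),
                                            type = "response")))
    },
    nb = {
      fit <- e1071::naiveBayes(y ~ ., data = df)
      function(newx) predict(fit, data.frame(newx), type = "raw")[, "1"]
    },
    dnn = {
      ctr <- colMeans(x_tr); scl <- apply(x_tr, 2, stats::sd)
      scl[scl == 0] <- 1
      xs <- sweep(sweep(x_tr, 2, ctr), 2, scl, "/")
      fit <- nnet::nnet(xs, matrix(y_tr, ncol = 1), size = 16,
                        decay = 1e-3, maxit = 300, entropy = TRUE,
                        trace = FALSE, MaxNWts = 5000)
      function(newx) {
        xs2 <- sweep(sweep(as.matrix(newx), 2, ctr), 2, scl, "/")
        as.numeric(predict(fit, xs2))
      }
    },
    stop("unknown baseline method: ", method, call. = FALSE)
  )
}

#' Benchmark conventional classifiers on fixed folds
#'
#' Evaluates a Gaussian-kernel support vector machine, logistic regression,
#' naive Bayes, and a backpropagation neural network trained by cross
#' entropy, on exactly the folds used for the AUC network (paired
#' comparison). Each method's operating point is chosen on a stratified
#' validation subset of its training portion (ROC point nearest (0,1)), and
#' per-fold balanced accuracy is reported with a median/interquartile
#' summary.
#'
#' @param x Feature matrix.
#' @param labels Two-level labels.
#' @param fold_id Integer fold assignment per row (as in [crossval()]'s
#'   `fold_id`).
#' @param methods Subset of `c("svm", "lr", "nb", "dnn")`.
#' @param val_fraction Validation fraction for the operating point.
#' @param seed Integer seed.
#' @return List of class `baseline_bench`: `balanced_accuracy` (matrix,
#'   folds x methods), `auc` (same shape), `summary` (median and IQR per
#'   method).
#' @export
baselines <- function(x, labels, fold_id, methods = c("svm", "lr", "nb",
                                                      "dnn"),
                      val_fraction = 0.2, seed = 1) {
  x <- as.matrix(x)
  y <- as.integer(factor(labels)) - 1L
  k <- max(fold_id)
  ba <- auc <- matrix(NA_real_, k, length(methods),
                      dimnames = list(NULL, methods))
  for (f in seq_len(k)) {
    test <- which(fold_id == f)
    tr <- which(fold_id != f)
    val <- tr[stratified_split(y[tr], val_fraction, seed + f)]
    fit_idx <- setdiff(tr, val)
    for (m in methods) {
      scorer <- fit_baseline(m, x[fit_idx, , drop = FALSE], y[fit_idx])
      thr <- operating_point(
        roc_threshold_scan(scorer(x[val, , drop = FALSE]), y[val]))
      s <- scorer(x[test, , drop = FALSE])
      ba[f, m] <- balanced_accuracy(s, y[test], thr)
      auc[f, m] <- auc_rank(s, y[test])
    }
  }
  summ <- data.frame(
    method = methods,
    median_ba = apply(ba, 2, stats::median),
    iqr_ba = apply(ba, 2, stats::IQR))
  structure(list(balanced_accuracy = ba, auc = auc, summary = summ),
            class = "baseline_bench")
}

#' Learning curves: cross-entropy versus training-set size
#'
#' For each requested size, draws a stratified training subset, trains the
#' scorer, and records binary cross-entropy on the training subset and on a
#' fixed held-out test set, averaged over `repeats` draws. The test curve
#' falls and the training curve rises in expectation as the sample grows;
#' their gap is the generalization error.
#'
#' @param x Feature matrix.
#' @param labels Two-level labels.
#' @param sizes Increasing training sizes; each must leave the test fraction
#'   intact.
#' @param control A [ga_control()] for the AUC-network trainer.
#' @param seed Integer seed.
#' @param repeats Training draws averaged per size.
#' @param test_fraction Held-out fraction for the test curve.
#' @param trainer Training function (default [ga_train()]).
#' @return Data frame: `size`, `train_xent`, `test_xent`, `gap`.
#' @export
learning_curves <- function(x, labels, sizes, control = ga_control(),
                            seed = 1, repeats = 3, test_fraction = 0.25,
                            trainer = ga_train) {
  x <- as.matrix(x)
  y <- as.integer(factor(labels)) - 1L
  test <- stratified_split(y, test_fraction, seed)
  pool <- setdiff(seq_along(y), test)
  if (max(sizes) > length(pool))
    stop("size exceeds available training data", call. = FALSE)
  xent <- function(p, yy) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(yy * log(p) + (1 - yy) * log(1 - p))
  }
  rows <- lapply(sizes, function(n) {
    tr_x <- te_x <- numeric(repeats)
    for (r in seq_len(repeats)) {
      set.seed(seed + 131 * n + r)
      sub <- pool[stratified_split(y[pool], n / length(pool),
                                   seed + 977 * n + r)]
      if (length(sub) > n) sub <- sub[seq_len(n)]
      fit <- trainer(x[sub, , drop = FALSE], y[sub], control,
                     seed = seed + r)
      tr_x[r] <- xent(predict_aucnet(fit, x[sub, , drop = FALSE]), y[sub])
      te_x[r] <- xent(predict_aucnet(fit, x[test, , drop = FALSE]), y[test])
    }
    data.frame(size = n, train_xent = mean(tr_x), test_xent = mean(te_x),
               gap = mean(te_x) - mean(tr_x))
  })
  do.call(rbind, rows)
}

#' First two principal components of the feature space
#'
#' PCA of the standardized 16-feature matrix: per-record scores on the first
#' two components and the explained-variance fractions, for visualizing the
#' class structure.
#'
#' @param records Records data frame or feature matrix (>= 3 rows).
#' @return List with `scores` (n x 2), `explained` (variance fractions for
#'   all components), `rotation`.
#' @export
pca_view <- function(records) {
  x <- if (is.data.frame(records)) feature_matrix(records) else
    as.matrix(records)
  if (nrow(x) < 3) stop("need at least 3 records", call. = FALSE)
  keep <- apply(x, 2, stats::sd) > 0
  p <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  list(scores = p$x[, 1:2, drop = FALSE],
       explained = p$sdev^2 / sum(p$sdev^2),
       rotation = p$rotation)
}
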