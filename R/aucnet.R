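# Feedforward network trained globally by a genetic algorithm on a
# regularized AUC cost, with ROC-by-bias-scan, cross-validation, balanced
# accuracy, baseline classifiers, learning curves and a PCA view.

sigmoid <- function(a) 1 / (1 + exp(-a))
relu <- function(a) { a[a < 0] <- 0; a }

#' Construct an AUC-network model
#'
#' Fully connected feedforward network: 16 inputs, three hidden layers of 48
#' rectified linear units, and one logistic-sigmoid output node. Every layer
#' carries a bias node of value 1; its incoming weight is the last row of
#' each weight matrix.
#'
#' @param layer_sizes Integer vector of node counts, input to output.
#' @param weights Optional list of weight matrices (`(n_in + 1) x n_out`);
#'   initialized N(0, `init_sd`) when `NULL`.
#' @param init_sd Weight initialization standard deviation.
#' @param seed Integer seed for the initialization.
#' @return An object of class `aucnet`.
#' @export
aucnet <- function(layer_sizes = c(16, 48, 48, 48, 1), weights = NULL,
                   init_sd = 0.1, seed = 1) {
  L <- length(layer_sizes) - 1
  if (is.null(weights)) {
    set.seed(seed)
    weights <- lapply(seq_len(L), function(l)
      matrix(stats::rnorm((layer_sizes[l] + 1) * layer_sizes[l + 1],
                          0, init_sd),
             layer_sizes[l] + 1, layer_sizes[l + 1]))
  }
  stopifnot(length(weights) == L)
  for (l in seq_len(L))
    stopifnot(nrow(weights[[l]]) == layer_sizes[l] + 1,
              ncol(weights[[l]]) == layer_sizes[l + 1])
  structure(list(layer_sizes = layer_sizes, weights = weights),
            class = "aucnet")
}

n_genes <- function(layer_sizes) {
  L <- length(layer_sizes) - 1
  sum(vapply(seq_len(L), function(l)
    (layer_sizes[l] + 1) * layer_sizes[l + 1], 0))
}

genes_to_weights <- function(genes, layer_sizes) {
  L <- length(layer_sizes) - 1
  out <- vector("list", L)
  pos <- 0
  for (l in seq_len(L)) {
    k <- (layer_sizes[l] + 1) * layer_sizes[l + 1]
    out[[l]] <- matrix(genes[(pos + 1):(pos + k)],
                       layer_sizes[l] + 1, layer_sizes[l + 1])
    pos <- pos + k
  }
  out
}

weights_to_genes <- function(weights) unlist(weights, use.names = FALSE)

# mean square of non-bias weights (the bias rows are excluded)
mean_sq_weights <- function(weights) {
  v <- unlist(lapply(weights, function(w) w[-nrow(w), ]), use.names = FALSE)
  mean(v^2)
}

#' Forward pass
#'
#' Each node emits the activation of a weighted sum of the previous layer's
#' outputs plus a bias node fixed at 1: hidden layers use the rectifier,
#' the output node the logistic sigmoid, so scores lie in (0,1).
#'
#' @param model An [aucnet()].
#' @param x Numeric matrix (rows = observations, 16 columns of standardized
#'   features) or a single feature vector.
#' @param upto Stop after this hidden layer and return its activations
#'   (internal use by the bias scan); `NULL` for the full pass.
#' @return Score vector in (0,1), or an activation matrix when `upto` is
#'   given.
#' @export
forward <- function(model, x, upto = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) stop("non-finite input features", call. = FALSE)
  a <- x
  L <- length(model$weights)
  last <- if (is.null(upto)) L else upto
  for (l in seq_len(last)) {
    z <- cbind(a, 1) %*% model$weights[[l]]
    a <- if (l < L) relu(z) else sigmoid(z)
  }
  if (is.null(upto)) as.numeric(a) else a
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney form: the probability that a random positive outscores a
#' random negative (ties counted half), computed from the rank sum.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (or two-level) labels.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  y <- as.integer(factor(labels)) - 1L
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(fpr, tpr, source) {
  o <- order(fpr, tpr)
  fpr <- c(0, fpr[o], 1); tpr <- c(0, tpr[o], 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc, source = source),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC %.4f (%s)\n",
              length(x$fpr), x$auc, x$source))
  invisible(x)
}

#' ROC by scanning the classification threshold on scores
#'
#' Standard threshold sweep over the sorted unique scores; points run from
#' (0,0) to (1,1) with non-decreasing rates, and the AUC is the trapezoidal
#' integral.
#'
#' @param scores Numeric scores.
#' @param labels Two-level labels.
#' @return A `roc_curve` (fields `fpr`, `tpr`, `auc`, `thresholds`).
#' @export
roc_threshold_scan <- function(scores, labels) {
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) != 2) stop("both classes required", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  # collapse tied scores to one operating point
  keep <- c(diff(ss) != 0, TRUE)
  tpr <- tp[keep] / sum(ys); fpr <- fp[keep] / sum(1 - ys)
  out <- roc_points(fpr, tpr, "threshold-scan")
  out$thresholds <- ss[keep]
  out
}

#' ROC by scanning the output bias weight
#'
#' Traces the ROC by shifting the weight of the bias node feeding the output
#' node across a range that saturates both ends of the curve: each shift
#' defines one classifier in the collection (score > 1/2 decides positive).
#' Because the sigmoid is monotone, this is equivalent to a threshold scan on
#' the fixed model's scores; the equivalence is asserted by the test suite.
#' The last hidden layer's activations are computed once and reused across
#' shifts.
#'
#' @param model An [aucnet()].
#' @param x Standardized feature matrix.
#' @param labels Two-level labels.
#' @return A `roc_curve` with `source = "bias-scan"`.
#' @export
roc_bias_scan <- function(model, x, labels) {
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) != 2) stop("both classes required", call. = FALSE)
  L <- length(model$weights)
  h <- forward(model, x, upto = L - 1)
  w_out <- model$weights[[L]]
  pre <- as.numeric(cbind(h, 1) %*% w_out)       # pre-sigmoid scores
  # bias shifts that move the decision boundary across every sample
  deltas <- c(-(sort(unique(pre)) + 1e-12), max(abs(pre)) + 1)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  tpr <- fpr <- numeric(length(deltas))
  for (i in seq_along(deltas)) {
    pos <- sigmoid(pre + deltas[i]) > 0.5
    tpr[i] <- sum(pos & y == 1) / n1
    fpr[i] <- sum(pos & y == 0) / n0
  }
  roc_points(fpr, tpr, "bias-scan")
}

#' Regularized AUC cost
#'
#' The training objective minimized by the genetic algorithm:
#' \deqn{C = (1 - \mathrm{AUC}) + \lambda \,\overline{w^2},}
#' where the mean square runs over all weights except those of the bias
#' nodes. With `lambda = 0` the cost reduces to `1 - AUC`.
#'
#' @param model An [aucnet()].
#' @param x Standardized feature matrix.
#' @param labels Two-level labels.
#' @param lambda Regularization parameter (>= 0).
#' @return Scalar cost.
#' @export
aucnet_cost <- function(model, x, labels, lambda = 1e-3) {
  (1 - auc_rank(forward(model, x), labels)) +
    lambda * mean_sq_weights(model$weights)
}

#' Genetic-algorithm training controls
#'
#' Hyperparameters of the evolutionary optimizer: population size,
#' tournament selection size, uniform-crossover rate, per-gene Gaussian
#' mutation, elitism, and validation-based early stopping.
#'
#' @param population Individuals per generation (>= 4).
#' @param generations Maximum generations.
#' @param tournament Tournament size for selection.
#' @param crossover_rate Probability a mating pair undergoes uniform
#'   crossover.
#' @param mutation_sd Gaussian mutation standard deviation.
#' @param mutation_rate Per-gene mutation probability.
#' @param elitism Individuals copied unchanged to the next generation.
#' @param init_sd Initialization standard deviation for weights.
#' @param patience Generations without validation-AUC improvement before
#'   early stop.
#' @param lambda Regularization parameter (used when `select_lambda` is
#'   `FALSE`).
#' @param lambda_grid Candidate lambdas for validation-based selection.
#' @param select_lambda Select lambda on validation AUC from `lambda_grid`
#'   (one GA run per candidate).
#' @param val_fraction Fraction of the training data held out for
#'   validation.
#' @return List of class `ga_control`.
#' @export
ga_control <- function(population = 100, generations = 500, tournament = 3,
                       crossover_rate = 0.7, mutation_sd = 0.1,
                       mutation_rate = 0.05, elitism = 1, init_sd = 0.1,
                       patience = 50, lambda = 1e-3,
                       lambda_grid = c(0, 1e-4, 1e-3, 1e-2),
                       select_lambda = FALSE, val_fraction = 0.2) {
  if (population < 4) stop("population must be at least 4", call. = FALSE)
  structure(as.list(environment()), class = "ga_control")
}

stratified_split <- function(y, fraction, seed) {
  set.seed(seed)
  idx <- unlist(lapply(split(seq_along(y), y), function(i)
    sample(i, max(1, round(fraction * length(i))))), use.names = FALSE)
  sort(idx)
}

ga_run <- function(x_tr, y_tr, x_val, y_val, layer_sizes, ctrl, lambda,
                   seed) {
  set.seed(seed)
  ng <- n_genes(layer_sizes)
  pop <- matrix(stats::rnorm(ng * ctrl$population, 0, ctrl$init_sd),
                ng, ctrl$population)
  eval_cost <- function(g) {
    w <- genes_to_weights(g, layer_sizes)
    m <- structure(list(layer_sizes = layer_sizes, weights = w),
                   class = "aucnet")
    aucnet_cost(m, x_tr, y_tr, lambda)
  }
  cost <- apply(pop, 2, eval_cost)
  best_val <- -Inf; best_val_cost <- Inf
  best_genes <- pop[, which.min(cost)]; stall <- 0
  mut_sd <- ctrl$mutation_sd
  best_cost_seen <- min(cost); cost_stall <- 0
  trace <- vector("list", ctrl$generations)
  for (gen in seq_len(ctrl$generations)) {
    elite <- order(cost)[seq_len(ctrl$elitism)]
    newpop <- matrix(0, ng, ctrl$population)
    newpop[, seq_len(ctrl$elitism)] <- pop[, elite]
    for (j in seq(ctrl$elitism + 1, ctrl$population, by = 2)) {
      pick <- function() {
        cand <- sample.int(ctrl$population, ctrl$tournament)
        cand[which.min(cost[cand])]
      }
      p1 <- pop[, pick()]; p2 <- pop[, pick()]
      if (stats::runif(1) < ctrl$crossover_rate) {
        swap <- stats::runif(ng) < 0.5
        tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
      }
      mut <- function(g) {
        hit <- stats::runif(ng) < ctrl$mutation_rate
        g[hit] <- g[hit] + stats::rnorm(sum(hit), 0, mut_sd)
        g
      }
      newpop[, j] <- mut(p1)
      if (j + 1 <= ctrl$population) newpop[, j + 1] <- mut(p2)
    }
    pop <- newpop
    cost <- apply(pop, 2, eval_cost)
    # anneal the mutation scale when the best training cost stalls: the
    # rank-based cost is piecewise constant, so fine-tuning needs
    # progressively smaller steps
    if (min(cost) < best_cost_seen - 1e-12) {
      best_cost_seen <- min(cost); cost_stall <- 0
    } else {
      cost_stall <- cost_stall + 1
      if (cost_stall >= 5) {
        mut_sd <- max(mut_sd / 2, ctrl$mutation_sd / 64)
        cost_stall <- 0
      }
    }
    bi <- which.min(cost)
    bw <- genes_to_weights(pop[, bi], layer_sizes)
    bm <- structure(list(layer_sizes = layer_sizes, weights = bw),
                    class = "aucnet")
    s_tr <- forward(bm, x_tr); s_val <- forward(bm, x_val)
    val_auc <- auc_rank(s_val, y_val)
    thr <- operating_point(roc_threshold_scan(s_val, y_val))
    trace[[gen]] <- data.frame(
      generation = gen, best_cost = cost[bi],
      train_auc = auc_rank(s_tr, y_tr), val_auc = val_auc,
      val_balanced_accuracy = balanced_accuracy(s_val, y_val, thr))
    # validation selects the model; ties (common when the validation subset
    # is small enough for its AUC to saturate) break on training cost, and
    # only generations improving neither count toward the patience
    if (val_auc > best_val + 1e-9 ||
        (val_auc >= best_val - 1e-9 && cost[bi] < best_val_cost - 1e-12)) {
      best_val <- max(best_val, val_auc)
      best_val_cost <- cost[bi]
      best_genes <- pop[, bi]; stall <- 0
    } else stall <- stall + 1
    if (stall >= ctrl$patience) break
  }
  list(genes = best_genes, val_auc = best_val,
       trace = do.call(rbind, trace))
}

#' Train the AUC network with a genetic algorithm
#'
#' Global optimization of the regularized AUC cost: tournament selection,
#' uniform crossover, per-gene Gaussian mutation, and elitism (so the best
#' training cost is non-increasing across generations). A stratified
#' validation split guides early stopping (patience on validation AUC) and,
#' optionally, the choice of the regularization parameter; the returned
#' model is the validation-best individual. Features are standardized with
#' the training-split statistics, which are stored in the model and applied
#' by [predict_aucnet()].
#'
#' @param x Feature matrix (raw scale; rows = cells).
#' @param labels Two-level class labels.
#' @param control A [ga_control()].
#' @param seed Integer seed; the run is deterministic given (data, control,
#'   seed).
#' @param hidden Hidden layer sizes.
#' @return List of class `aucnet_fit`: `model`, `center`/`scale`,
#'   `lambda`, `trace` (per-generation best cost and accuracies),
#'   `operating_threshold` (validation ROC point nearest (0,1)).
#' @export
ga_train <- function(x, labels, control = ga_control(), seed = 1,
                     hidden = c(48, 48, 48)) {
  x <- as.matrix(x)
  y <- as.integer(factor(labels)) - 1L
  layer_sizes <- c(ncol(x), hidden, 1)
  val_idx <- stratified_split(y, control$val_fraction, seed + 1000L)
  ctr <- colMeans(x[-val_idx, , drop = FALSE])
  scl <- apply(x[-val_idx, , drop = FALSE], 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  x_tr <- xs[-val_idx, , drop = FALSE]; y_tr <- y[-val_idx]
  x_val <- xs[val_idx, , drop = FALSE]; y_val <- y[val_idx]
  lambdas <- if (control$select_lambda) control$lambda_grid else
    control$lambda
  runs <- lapply(seq_along(lambdas), function(i)
    ga_run(x_tr, y_tr, x_val, y_val, layer_sizes, control, lambdas[i],
           seed + i - 1L))
  best <- which.max(vapply(runs, function(r) r$val_auc, 0))
  run <- runs[[best]]
  model <- aucnet(layer_sizes,
                  weights = genes_to_weights(run$genes, layer_sizes))
  s_val <- forward(model, x_val)
  thr <- operating_point(roc_threshold_scan(s_val, y_val))
  structure(list(model = model, center = ctr, scale = scl,
                 lambda = lambdas[best], trace = run$trace,
                 operating_threshold = thr,
                 classes = levels(factor(labels))),
            class = "aucnet_fit")
}

#' @rdname ga_train
#' @param fit An `aucnet_fit`.
#' @param newx Feature matrix on the raw scale.
#' @return `predict_aucnet`: scores in (0,1).
#' @export
predict_aucnet <- function(fit, newx) {
  xs <- sweep(sweep(as.matrix(newx), 2, fit$center), 2, fit$scale, "/")
  forward(fit$model, xs)
}

#' Operating point of an ROC curve
#'
#' The ROC point minimizing the Euclidean distance to the perfect corner
#' (0,1); returns the corresponding score threshold when the curve carries
#' thresholds (threshold scan), otherwise the point index.
#'
#' @param roc A `roc_curve`.
#' @return Score threshold (or index).
#' @export
operating_point <- function(roc) {
  d <- roc$fpr^2 + (1 - roc$tpr)^2
  i <- which.min(d)
  if (!is.null(roc$thresholds)) {
    # curve points are offset by the prepended (0,0)
    j <- max(1, min(length(roc$thresholds), i - 1))
    roc$thresholds[j]
  } else i
}

#' Balanced accuracy at an operating point
#'
#' Mean of sensitivity and specificity, `(TPR + TNR)/2`, in percent; 50% for
#' chance in binary classification regardless of class imbalance.
#'
#' @param scores Numeric scores.
#' @param labels Two-level labels.
#' @param threshold Decision threshold on the scores (predict positive when
#'   `score >= threshold`).
#' @return Percentage in \[0, 100\].
#' @export
balanced_accuracy <- function(scores, labels, threshold = 0.5) {
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) != 2) stop("both classes required", call. = FALSE)
  pos <- scores >= threshold
  tpr <- sum(pos & y == 1) / sum(y == 1)
  tnr <- sum(!pos & y == 0) / sum(y == 0)
  (tpr + tnr) / 2 * 100
}

#' Stratified k-fold cross-validation of the AUC network
#'
#' Splits the records into `k` disjoint, stratified test folds; within each
#' training portion a validation subset steers early stopping and the
#' operating point. Reports the per-fold test ROC (threshold scan), AUC and
#' balanced accuracy.
#'
#' @param x Feature matrix.
#' @param labels Two-level labels (each class must have at least `k`
#'   members).
#' @param k Number of folds (>= 2).
#' @param control A [ga_control()].
#' @param seed Integer seed.
#' @param trainer Training function with the signature of [ga_train()];
#'   substitute to cross-validate another scorer.
#' @return List of class `aucnet_cv`: `folds` (per-fold list with `roc`,
#'   `auc`, `balanced_accuracy`, `test_idx`), `mean_auc`,
#'   `mean_balanced_accuracy`.
#' @export
crossval <- function(x, labels, k = 5, control = ga_control(), seed = 1,
                     trainer = ga_train) {
  x <- as.matrix(x)
  y <- as.integer(factor(labels)) - 1L
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (min(table(y)) < k)
    stop("each class needs at least k members", call. = FALSE)
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    fold_id[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  folds <- lapply(seq_len(k), function(f) {
    test <- which(fold_id == f)
    fit <- trainer(x[-test, , drop = FALSE], y[-test], control,
                   seed = seed + f)
    s <- predict_aucnet(fit, x[test, , drop = FALSE])
    roc <- roc_threshold_scan(s, y[test])
    list(roc = roc, auc = roc$auc,
         balanced_accuracy = balanced_accuracy(s, y[test],
                                               fit$operating_threshold),
         test_idx = test, lambda = fit$lambda)
  })
  structure(list(
    folds = folds, fold_id = fold_id,
    mean_auc = mean(vapply(folds, function(f) f$auc, 0)),
    mean_balanced_accuracy =
      mean(vapply(folds, function(f) f$balanced_accuracy, 0))),
    class = "aucnet_cv")
}

#' @export
print.aucnet_cv <- function(x, ...) {
  cat(sprintf("<aucnet_cv> %d folds: mean AUC %.3f, mean balanced accuracy %.1f%%\n",
              length(x$folds), x$mean_auc, x$mean_balanced_accuracy))
  invisible(x)
}
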