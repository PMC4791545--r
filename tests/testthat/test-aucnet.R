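# AUC network: forward pass, ROC oracles, cost, GA training, balanced
# accuracy, cross-validation.

test_that("forward pass matches hand computation", {
  m0 <- aucnet(c(2, 1, 1), weights = list(matrix(0, 3, 1), matrix(0, 2, 1)))
  expect_equal(forward(m0, c(1, 2)), 0.5)      # sigmoid(0)
  # single hidden unit, hand-set: relu(w.x + b) then sigmoid(v.h + c)
  w <- c(0.5, -1); b <- 0.3; v <- 2; cc <- -0.1
  m1 <- aucnet(c(2, 1, 1),
               weights = list(matrix(c(w, b), 3, 1), matrix(c(v, cc), 2, 1)))
  x <- c(1.2, 0.4)
  h <- max(0, sum(w * x) + b)
  expect_equal(forward(m1, x), 1 / (1 + exp(-(v * h + cc))))
  # scaling the output weights saturates the sigmoid
  m2 <- m1; m2$weights[[2]] <- m1$weights[[2]] * 1e4
  expect_true(forward(m2, x) > 1 - 1e-10 || forward(m2, x) < 1e-10)
  expect_error(forward(m1, c(NA, 1)), "finite")
})

test_that("bias-scan, threshold-scan, and rank AUC agree everywhere", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 60
    x <- matrix(rnorm(n * 16), n)
    y <- rep(c(0, 1), n / 2)
    model <- aucnet(seed = rep)
    s <- forward(model, x)
    a_rank <- auc_rank(s, y)
    a_thr <- roc_threshold_scan(s, y)$auc
    a_bias <- roc_bias_scan(model, x, y)$auc
    expect_equal(a_thr, a_rank, tolerance = 1e-12)
    expect_equal(a_bias, a_rank, tolerance = 1e-12)
    # agreement with the Mann-Whitney U statistic
    u <- wilcox.test(s[y == 1], s[y == 0], exact = FALSE)$statistic
    expect_equal(as.numeric(u) / (sum(y) * sum(1 - y)), a_rank,
                 tolerance = 1e-12)
  }
})

test_that("AUC handles the frozen examples and monotone invariance", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_threshold_scan(c(0.9, 0.8, 0.4, 0.2),
                                  c(1, 1, 0, 0))$auc, 1)
  # 2 of 4 pairs concordant
  expect_equal(auc_rank(c(0.9, 0.2, 0.8, 0.4), c(1, 1, 0, 0)), 0.5)
  set.seed(5)
  s <- runif(500); y <- rep(0:1, 250)
  expect_equal(auc_rank(exp(3 * s) - 1, y), auc_rank(s, y))
  # null scores give AUC 1/2
  set.seed(9)
  expect_lt(abs(auc_rank(rnorm(10000), rep(0:1, 5000)) - 0.5), 0.02)
})

test_that("the cost is regularized 1 - AUC", {
  n <- 40
  set.seed(2)
  x <- matrix(rnorm(n * 2), n)
  y <- as.integer(x[, 1] > 0)
  # a perfect linear classifier through a single hidden unit
  m <- aucnet(c(2, 1, 1),
              weights = list(matrix(c(10, 0, 5), 3, 1),
                             matrix(c(1, 0), 2, 1)))
  expect_equal(aucnet_cost(m, x, y, lambda = 0), 0, tolerance = 1e-12)
  # all weights 2: constant scores, tied ranks -> AUC 1/2; mean(w^2) = 4
  m2 <- aucnet(c(16, 48, 48, 48, 1))
  m2$weights <- lapply(m2$weights, function(w) w * 0 + 2)
  x16 <- matrix(rnorm(20 * 16), 20)
  y16 <- rep(0:1, 10)
  expect_equal(aucnet_cost(m2, x16, y16, lambda = 1), 0.5 + 4)
  # cost strictly increases with lambda at fixed weights
  expect_gt(aucnet_cost(m2, x16, y16, 1e-2),
            aucnet_cost(m2, x16, y16, 1e-3))
})

test_that("balanced accuracy follows its definition", {
  scores <- c(rep(0.9, 9), 0.1,  rep(0.9, 2), rep(0.1, 8))
  labels <- c(rep(1, 10), rep(0, 10))
  expect_equal(balanced_accuracy(scores, labels, 0.5), 85)
  expect_equal(balanced_accuracy(labels, labels, 0.5), 100)
  expect_equal(balanced_accuracy(rep(1, 20), labels, 0.5), 50)
  expect_error(balanced_accuracy(scores, rep(1, 20)), "both classes")
})

test_that("GA training learns separable data near the Bayes limit", {
  set.seed(1)
  n <- 1000                                  # 500 per class
  x <- matrix(rnorm(n * 16), n)
  y <- rep(0:1, n / 2)
  x[, 3] <- x[, 3] + ifelse(y == 1, 2, -2)   # d' = 4, Bayes AUC 0.998
  ctrl <- ga_control(population = 40, generations = 80, patience = 40)
  fit <- ga_train(x[1:700, ], y[1:700], ctrl, seed = 11)
  s <- predict_aucnet(fit, x[701:1000, ])
  expect_gte(auc_rank(s, y[701:1000]), 0.95)
  # determinism: identical weights for identical seeds
  fit2 <- ga_train(x[1:700, ], y[1:700], ctrl, seed = 11)
  expect_identical(fit$model$weights, fit2$model$weights)
  # elitism: best training cost never increases
  expect_true(all(diff(fit$trace$best_cost) <= 1e-12))
  expect_error(ga_control(population = 3), "population")
})

test_that("regularization shrinks the trained weights", {
  set.seed(4)
  n <- 120
  x <- matrix(rnorm(n * 16), n)
  y <- rep(0:1, n / 2)
  x[, 1] <- x[, 1] + ifelse(y == 1, 1.5, -1.5)
  ctrl0 <- ga_control(population = 16, generations = 12, patience = 12,
                      lambda = 0)
  ctrl1 <- ga_control(population = 16, generations = 12, patience = 12,
                      lambda = 0.5)
  f0 <- ga_train(x, y, ctrl0, seed = 2)
  f1 <- ga_train(x, y, ctrl1, seed = 2)
  msw <- function(f) mean(unlist(lapply(f$model$weights,
                                        function(w) w[-nrow(w), ]^2)))
  expect_lte(msw(f1), msw(f0))
})

test_that("cross-validation folds partition the data stratified", {
  set.seed(6)
  x <- matrix(rnorm(100 * 16), 100)
  y <- rep(0:1, 50)
  x[, 2] <- x[, 2] + ifelse(y == 1, 2.5, -2.5)
  ctrl <- ga_control(population = 8, generations = 3, patience = 3)
  cv <- crossval(x, y, k = 5, control = ctrl, seed = 3)
  idx <- sort(unlist(lapply(cv$folds, function(f) f$test_idx)))
  expect_equal(idx, 1:100)                   # disjoint and exhaustive
  expect_equal(vapply(cv$folds, function(f) length(f$test_idx), 0),
               rep(20, 5))
  for (f in cv$folds) {
    expect_true(all(diff(f$roc$fpr) >= 0))
    expect_true(all(diff(f$roc$tpr) >= 0))
  }
  expect_error(crossval(x, y, k = 60, control = ctrl), "at least k")
})

test_that("per-fold AUC is stable on fully separable data", {
  set.seed(6)
  n <- 500
  x <- matrix(rnorm(n * 16), n)
  y <- rep(0:1, n / 2)
  x[, 2] <- x[, 2] + ifelse(y == 1, 3, -3)   # d' = 6
  ctrl <- ga_control(population = 30, generations = 40, patience = 20)
  cv <- crossval(x, y, k = 5, control = ctrl, seed = 3)
  aucs <- vapply(cv$folds, function(f) f$auc, 0)
  expect_lt(diff(range(aucs)), 0.05)
  expect_gt(mean(aucs), 0.97)
})

test_that("PCA view reports explained variance correctly", {
  set.seed(8)
  # points on a line
  t <- rnorm(200)
  line <- cbind(t, 2 * t, -t) + matrix(rnorm(600, 0, 1e-6), 200)
  p <- pca_view(line)
  expect_gt(p$explained[1], 0.999)
  # anisotropic 2-D Gaussian, sd 3 and 1, at 45 degrees so both observed
  # axes share the variance: the 9:1 eigenvalue ratio survives
  # standardization -> explained fractions 0.9 / 0.1
  a <- pi / 4
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  p2 <- pca_view(cbind(rnorm(4000, 0, 3), rnorm(4000, 0, 1)) %*% rot)
  expect_equal(p2$explained[1], 0.9, tolerance = 0.02)
  expect_error(pca_view(line[1:2, ]), "at least 3")
})
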