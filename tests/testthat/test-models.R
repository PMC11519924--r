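# Oracles: the closed-form soft-threshold / normal-equations solutions
# are computed inline and the SGD fits must match them.

gd_spec <- function(kind, lr = 0.1, ...) {
  # deterministic full-batch settings used for oracle comparisons
  model_spec(kind, lr = lr, epochs = 3000, batch_size = NULL,
             lr_decay = 0.02, standardize = FALSE, ...)
}

test_that("MLR with alpha = 0 matches the normal-equations solution", {
  set.seed(10)
  n <- 80
  X <- qr.Q(qr(matrix(rnorm(n * 3), n, 3))) * sqrt(n)  # orthonormal-ish
  w_true <- c(1.5, -2, 0.7)
  y <- drop(X %*% w_true) + 0.3
  fit <- fit_mlr(X, y, gd_spec("MLR", alpha = 0, lr = 0.2))
  w_ols <- unname(coef(lm(y ~ X))[-1])
  expect_equal(unname(fit$w), w_ols, tolerance = 1e-6)
  expect_equal(fit$beta, unname(coef(lm(y ~ X))[1]), tolerance = 1e-5)
})

test_that("1-D Lasso matches the soft-threshold closed form", {
  set.seed(11)
  n <- 80
  x <- as.numeric(scale(rnorm(n)))
  y <- 2 * x + 0.5
  alpha <- 0.1
  fit <- fit_mlr(matrix(x), y, gd_spec("MLR", alpha = alpha))
  w_ols <- sum(x * y) / sum(x^2)
  thresh <- alpha * n / sum(x^2)
  expected <- sign(w_ols) * max(abs(w_ols) - thresh, 0)
  expect_equal(unname(fit$w), expected, tolerance = 1e-4)
})

test_that("constant response yields zero weights and matching intercept", {
  set.seed(12)
  X <- matrix(rnorm(60 * 2), 60, 2)
  fit <- fit_mlr(X, rep(7, 60), gd_spec("MLR", alpha = 0.1))
  expect_lt(max(abs(fit$w)), 1e-3)
  expect_equal(fit$beta, 7, tolerance = 1e-3)
})

test_that("training loss is monotone nonincreasing under full-batch decay", {
  set.seed(13)
  X <- matrix(rnorm(50 * 2), 50, 2)
  y <- drop(X %*% c(1, -1)) + rnorm(50, 0, 0.1)
  for (alpha in c(0, 0.1)) {
    fit <- fit_mlr(X, y, model_spec("MLR", alpha = alpha, lr = 0.05,
                                    epochs = 200, batch_size = NULL,
                                    lr_decay = 0.05))
    expect_true(all(diff(fit$loss_curve) <= 1e-8))
  }
})

test_that("fits are bit-reproducible under a fixed seed", {
  set.seed(14)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- drop(X %*% c(1, 2, -1)) + rnorm(60)
  f1 <- fit_mlr(X, y, model_spec("MLR", seed = 99))
  f2 <- fit_mlr(X, y, model_spec("MLR", seed = 99))
  expect_identical(f1$w, f2$w)
  expect_identical(f1$loss_curve, f2$loss_curve)
  f3 <- fit_svr(X, y, model_spec("SVR", seed = 99))
  f4 <- fit_svr(X, y, model_spec("SVR", seed = 99))
  expect_identical(f3$w, f4$w)
})

test_that("PR recovers a quadratic target and shrinks unused squares", {
  x <- seq(-2, 2, length.out = 50)
  y <- 2 + 3 * x^2
  fit <- fit_pr(matrix(x), y, gd_spec("PR", alpha = 0))
  expect_equal(unname(fit$w[2]), 3, tolerance = 1e-3)
  # linear ground truth: the quadratic weight shrinks under L1
  y_lin <- 1 + 2 * x
  f_l1 <- fit_pr(matrix(x), y_lin, gd_spec("PR", alpha = 0.1))
  expect_lt(abs(f_l1$w[2]), abs(f_l1$w[1]) / 10)
  expect_error(fit_pr(matrix(numeric(0), 5, 0), rnorm(5)), "empty")
})

test_that("SVR attains zero slack when all residuals sit inside the tube", {
  set.seed(15)
  x <- runif(40, -2, 2)
  y <- 1.5 * x + 2 + runif(40, -0.3, 0.3)  # all within eps = 1 of the line
  fit <- fit_svr(matrix(x), y, gd_spec("SVR"))
  r <- y - predict(fit, matrix(x))
  slack <- sum(pmax(abs(r) - 1, 0))
  expect_lt(slack, 0.05)
})

test_that("SVR recovers a noiseless wide-range slope", {
  x <- seq(-50, 50, length.out = 60)
  y <- 5 * x
  fit <- fit_svr(matrix(x), y, gd_spec("SVR"))
  slope <- (predict(fit, matrix(50)) - predict(fit, matrix(-50))) / 100
  expect_equal(unname(slope), 5, tolerance = 0.05)
})

test_that("SVR agrees with an established implementation", {
  skip_if_not_installed("e1071")
  set.seed(16)
  X <- matrix(runif(50, -3, 3))
  y <- 5 * X[, 1] + rnorm(50, 0, 0.3)
  fit <- fit_svr(X, y, gd_spec("SVR"))
  ref <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                    cost = 1.5, epsilon = 1, scale = FALSE)
  rms <- sqrt(mean((predict(fit, X) - predict(ref, X))^2))
  expect_lt(rms, 0.05)
})

test_that("DTR predicts constants, recovers step functions, respects depth", {
  X <- matrix(seq(0, 1, length.out = 30))
  f_const <- fit_dtr(X, rep(4, 30))
  expect_true(f_const$tree$leaf)
  expect_equal(predict(f_const, X), rep(4, 30))
  # 2-step function is exactly recoverable within depth 3
  y_step <- ifelse(X[, 1] < 0.3, 1, ifelse(X[, 1] < 0.7, 5, 9))
  f_step <- fit_dtr(X, y_step)
  expect_equal(predict(f_step, X), y_step)
  # depth bound holds on arbitrary data
  set.seed(17)
  Xr <- matrix(rnorm(200 * 3), 200, 3)
  yr <- rnorm(200)
  f_r <- fit_dtr(Xr, yr)
  expect_lte(chromox:::tree_depth(f_r$tree), 3)
})

test_that("DTR is invariant to monotone feature rescaling", {
  set.seed(18)
  X <- matrix(rnorm(100 * 2), 100, 2)
  y <- ifelse(X[, 1] > 0, 3, -1) + rnorm(100, 0, 0.1)
  f1 <- fit_dtr(X, y)
  X2 <- X
  X2[, 1] <- exp(X[, 1])  # strictly monotone transform, fit and predict
  f2 <- fit_dtr(X2, y)
  expect_equal(predict(f2, X2), predict(f1, X))
})

test_that("the network learns a linear target and early stopping fires", {
  set.seed(19)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- drop(X %*% c(1, -2, 0.5, 1.5, -1)) + 3
  fit <- fit_nn(X, y, model_spec("NN", lr = 0.03, epochs = 800))
  val_rmse <- sqrt(mean((y[fit$val_idx] -
                           predict(fit, X[fit$val_idx, , drop = FALSE]))^2))
  expect_lt(val_rmse, 0.1 * sd(y))
  # early stopping: stopped strictly before the epoch cap, after exactly
  # `patience` non-improving epochs
  expect_true(fit$converged)
  expect_lt(fit$stopped_epoch, 800)
  best_epoch <- which.min(fit$val_curve)
  expect_equal(fit$stopped_epoch - best_epoch, fit$spec$patience)
  expect_error(fit_nn(X[, 1:3], y), "5 features")
})

test_that("the network finds no signal in permuted targets", {
  set.seed(20)
  X <- matrix(rnorm(150 * 5), 150, 5)
  y <- drop(X %*% c(1, -2, 0.5, 1.5, -1))
  y_perm <- sample(y)
  fit <- fit_nn(X, y_perm, model_spec("NN", lr = 0.02, epochs = 100))
  rmse <- sqrt(mean((y_perm - predict(fit, X))^2))
  expect_gt(rmse, 0.6 * sd(y_perm))
})

test_that("logistic classification separates separable data and stays calibrated", {
  set.seed(21)
  n <- 100
  X <- matrix(rnorm(n * 2), n, 2)
  labels <- as.numeric(X[, 1] + 0.5 * X[, 2] > 0)
  fit <- fit_logistic(X, labels, model_spec("LOGISTIC", alpha = 0, lr = 0.5,
                                            epochs = 400))
  acc <- mean(predict(fit, X, type = "class") == labels)
  expect_gt(acc, 0.97)
  # balanced random labels give p near 0.5
  set.seed(22)
  rnd <- sample(rep(0:1, n / 2))
  f2 <- fit_logistic(X, rnd, model_spec("LOGISTIC", alpha = 0, lr = 0.1,
                                        epochs = 200))
  expect_lt(abs(mean(predict(f2, X)) - 0.5), 0.1)
  # probabilities are clipped so the loss is finite
  expect_true(all(is.finite(f2$loss_curve)))
  p <- predict(fit, X * 100)
  expect_true(all(p >= 1e-12 & p <= 1 - 1e-12))
  expect_error(fit_logistic(X, rep(1, n)), "both classes")
})

test_that("K-fold partition covers every sample exactly once", {
  folds <- kfold_indices(20, K = 10, seed = 5)
  expect_length(folds, 10)
  expect_true(all(lengths(folds) == 2))
  expect_equal(sort(unlist(folds)), 1:20)
  # uneven n: fold sizes differ by at most one
  f2 <- kfold_indices(23, K = 10, seed = 5)
  expect_lte(diff(range(lengths(f2))), 1)
  expect_equal(sort(unlist(f2)), 1:23)
  expect_error(kfold_indices(5, K = 10), "at least K")
})

test_that("cross-validated RMSE prefers the generating model over intercept-only", {
  set.seed(23)
  X <- matrix(rnorm(100 * 2), 100, 2)
  y <- drop(X %*% c(2, -1)) + rnorm(100, 0, 0.5)
  cv_lm <- kfold_cv(X, y, function(Xtr, ytr) {
    fit_mlr(Xtr, ytr, model_spec("MLR", alpha = 0, lr = 0.1, epochs = 300,
                                 batch_size = NULL))
  }, K = 10, seed = 9)
  cv_null <- kfold_cv(X, y, function(Xtr, ytr) {
    structure(list(kind = "MLR", std = NULL,
                   w = rep(0, ncol(Xtr)), beta = mean(ytr)),
              class = "chromox_fit")
  }, K = 10, seed = 9)
  expect_length(cv_lm$cv_rmse, 10)
  expect_lt(mean(cv_lm$cv_rmse), mean(cv_null$cv_rmse))
})

test_that("fitted models survive a JSON round trip", {
  set.seed(24)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- drop(X %*% c(1, 0, -2)) + 5
  path <- tempfile(fileext = ".json")
  fit <- fit_mlr(X, y, model_spec("MLR", alpha = 0, epochs = 100))
  write_fit_json(fit, path)
  back <- read_fit_json(path)
  expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-10)
  tree <- fit_dtr(X, y)
  write_fit_json(tree, path)
  expect_equal(predict(read_fit_json(path), X), predict(tree, X))
})
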