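#' Model specification
#'
#' Bundles the model kind with its hyperparameters and stochastic
#' gradient descent (SGD) settings. Defaults follow the detection
#' strategy's published choices: L1 degree `alpha = 0.1` for the
#' Lasso-regularized linear (MLR) and polynomial (PR) regressions,
#' `C = 1.5` and `epsilon = 1` for the linear-kernel support vector
#' regression (SVR), maximum depth 3 for the CART regression tree
#' (DTR), hidden layers of 64, 32, 16 and 5 neurons for the fully
#' connected network (NN), and early stopping at 15 epochs of no
#' validation improvement.
#'
#' @param kind one of `"MLR"`, `"PR"`, `"SVR"`, `"DTR"`, `"NN"`,
#'   `"LOGISTIC"`.
#' @param alpha L1 regularization degree for MLR/PR.
#' @param svr_c,svr_eps SVR box constraint and insensitive-tube width.
#' @param max_depth maximum DTR depth.
#' @param nn_layers hidden-layer widths of the network.
#' @param lr,lr_decay,epochs,batch_size SGD settings: base learning
#'   rate, per-epoch 1/t decay constant, number of epochs, minibatch
#'   size (`NULL` = full batch).
#' @param seed RNG seed making fits bit-reproducible.
#' @param patience early-stopping patience in epochs (NN).
#' @param val_frac validation fraction held out for early stopping (NN).
#' @param standardize learn feature means/scales on the training data
#'   and apply them at prediction time.
#' @param average_tail fraction of final epochs whose iterates are
#'   averaged into the reported weights (0 = last iterate). Averaging
#'   damps the SGD noise floor; it applies to MLR/PR/SVR/LOGISTIC.
#' @return An object of class `chromox_spec`.
#' @export
model_spec <- function(kind = c("MLR", "PR", "SVR", "DTR", "NN", "LOGISTIC"),
                       alpha = 0.1, svr_c = 1.5, svr_eps = 1, max_depth = 3,
                       nn_layers = c(64, 32, 16, 5),
                       lr = 0.01, lr_decay = 0.01, epochs = 500,
                       batch_size = 16, seed = 20240101,
                       patience = 15, val_frac = 0.2,
                       standardize = TRUE, average_tail = 0.25) {
  kind <- match.arg(kind)
  stopifnot(alpha >= 0, svr_c > 0, svr_eps >= 0, max_depth >= 1,
            lr > 0, epochs >= 1)
  structure(as.list(environment()), class = "chromox_spec")
}

as_feature_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  X
}

std_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

std_apply <- function(X, std) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

new_fit <- function(kind, spec, std, ...) {
  structure(c(list(kind = kind, spec = spec, std = std), list(...)),
            class = "chromox_fit")
}

# Minibatch SGD over per-sample subgradients. grad_fn(w, b, Xb, yb)
# returns list(gw, gb) for the minibatch; loss_fn(w, b) is the full
# objective recorded once per epoch. Learning rate decays as
# lr / (1 + lr_decay * epoch); the reported weights are the tail
# average of the per-epoch iterates.
sgd_optimize <- function(X, y, spec, grad_fn, loss_fn) {
  n <- nrow(X); p <- ncol(X)
  w <- rep(0, p); b <- 0
  bs <- if (is.null(spec$batch_size)) n else min(spec$batch_size, n)
  loss <- numeric(spec$epochs)
  tail_from <- max(1, ceiling(spec$epochs * (1 - spec$average_tail)))
  w_acc <- rep(0, p); b_acc <- 0; n_acc <- 0
  old_seed <- set_local_seed(spec$seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  for (epoch in seq_len(spec$epochs)) {
    lr_t <- spec$lr / (1 + spec$lr_decay * (epoch - 1))
    idx <- sample.int(n)
    for (start in seq(1, n, by = bs)) {
      batch <- idx[start:min(start + bs - 1, n)]
      g <- grad_fn(w, b, X[batch, , drop = FALSE], y[batch])
      w <- w - lr_t * g$gw
      b <- b - lr_t * g$gb
    }
    loss[epoch] <- loss_fn(w, b)
    if (epoch >= tail_from) {
      w_acc <- w_acc + w; b_acc <- b_acc + b; n_acc <- n_acc + 1
    }
  }
  list(w = w_acc / n_acc, b = b_acc / n_acc, loss_curve = loss)
}

set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Lasso-regularized multiple linear regression by SGD
#'
#' Minimizes `1/(2n) * sum((y - X w - beta)^2) + alpha * sum(|w|)` by
#' minibatch SGD, taking the L1 subgradient (0 at 0). With `alpha = 0`
#' this is ordinary least squares; with standardized features the
#' one-dimensional solution is the soft-thresholded OLS weight, which
#' serves as the closed-form oracle in the test suite. The intercept is
#' never penalized.
#'
#' @param X feature matrix (or data frame), one row per sample.
#' @param y numeric response.
#' @param spec a [model_spec()]; `spec$alpha`, SGD settings and the seed
#'   are honoured.
#' @return A `chromox_fit` with elements `w` (weights on the
#'   standardized or raw feature scale as configured), `beta`
#'   (intercept), `loss_curve`, and the standardization parameters.
#' @export
fit_mlr <- function(X, y, spec = model_spec("MLR")) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  stopifnot(all(is.finite(y)), nrow(X) == length(y))
  if (nrow(X) < ncol(X) + 2) stop("need n >= p + 2 samples", call. = FALSE)
  std <- if (spec$standardize) std_fit(X) else list(center = rep(0, ncol(X)),
                                                    scale = rep(1, ncol(X)))
  Xs <- std_apply(X, std)
  alpha <- spec$alpha
  grad_fn <- function(w, b, Xb, yb) {
    r <- yb - Xb %*% w - b
    list(gw = -crossprod(Xb, r)[, 1] / length(yb) + alpha * sign(w),
         gb = -mean(r))
  }
  loss_fn <- function(w, b) {
    r <- y - Xs %*% w - b
    sum(r^2) / (2 * length(y)) + alpha * sum(abs(w))
  }
  opt <- sgd_optimize(Xs, y, spec, grad_fn, loss_fn)
  new_fit("MLR", spec, std, w = opt$w, beta = opt$b,
          loss_curve = opt$loss_curve, features = colnames(X))
}

#' Polynomial regression with squared features
#'
#' Augments every feature with its square and fits the same
#' Lasso-regularized objective as [fit_mlr()], so each factor enters
#' with a linear and a quadratic weight plus the shared constant.
#'
#' @inheritParams fit_mlr
#' @export
fit_pr <- function(X, y, spec = model_spec("PR")) {
  X <- as_feature_matrix(X)
  if (ncol(X) == 0) stop("empty feature set", call. = FALSE)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(X)))
  Xp <- cbind(X, X^2)
  colnames(Xp) <- c(nm, paste0(nm, "_sq"))
  fit <- fit_mlr(Xp, y, spec)
  fit$kind <- "PR"
  fit
}

#' Epsilon-insensitive support vector regression by SGD
#'
#' Linear-kernel SVR trained on the primal objective
#' `1/2 ||w||^2 + C * sum(zeta + zeta*)`, where the slacks measure
#' excursions beyond the epsilon-insensitive tube. The SGD update uses
#' the (scale-normalized) subgradient of the equivalent per-sample
#' objective `||w||^2/(2n) + C * mean(max(0, |r| - eps))`; the intercept
#' is unregularized.
#'
#' @inheritParams fit_mlr
#' @export
fit_svr <- function(X, y, spec = model_spec("SVR")) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  stopifnot(all(is.finite(y)), nrow(X) == length(y))
  std <- if (spec$standardize) std_fit(X) else list(center = rep(0, ncol(X)),
                                                    scale = rep(1, ncol(X)))
  Xs <- std_apply(X, std)
  n <- nrow(Xs); C <- spec$svr_c; eps <- spec$svr_eps
  grad_fn <- function(w, b, Xb, yb) {
    r <- (yb - Xb %*% w - b)[, 1]
    active <- abs(r) > eps
    s <- ifelse(active, -sign(r), 0)
    list(gw = w / n + C * crossprod(Xb, s)[, 1] / length(yb),
         gb = C * mean(s))
  }
  loss_fn <- function(w, b) {
    r <- y - Xs %*% w - b
    sum(w^2) / 2 + C * sum(pmax(abs(r) - eps, 0))
  }
  opt <- sgd_optimize(Xs, y, spec, grad_fn, loss_fn)
  new_fit("SVR", spec, std, w = opt$w, beta = opt$b,
          loss_curve = opt$loss_curve, features = colnames(X))
}

#' Depth-limited CART regression tree
#'
#' Classic variance-reduction CART: each split minimizes the summed
#' squared error of the two children; leaves predict the mean of their
#' targets. Depth is capped (default 3, the published setting). Ties
#' between equally good splits go to the lowest feature index, then the
#' lowest threshold.
#'
#' @inheritParams fit_mlr
#' @export
fit_dtr <- function(X, y, spec = model_spec("DTR")) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1)
  tree <- grow_tree(X, y, depth = 0, max_depth = spec$max_depth)
  new_fit("DTR", spec, std = NULL, tree = tree, features = colnames(X))
}

grow_tree <- function(X, y, depth, max_depth) {
  if (depth >= max_depth || length(y) < 2 || stats::var(y) == 0) {
    return(list(leaf = TRUE, value = mean(y), n = length(y), depth = depth))
  }
  best <- NULL
  base_sse <- sum((y - mean(y))^2)
  best_sse <- base_sse - 1e-12
  for (j in seq_len(ncol(X))) {
    xv <- X[, j]
    cuts <- sort(unique(xv))
    if (length(cuts) < 2) next
    thr <- (cuts[-1] + cuts[-length(cuts)]) / 2
    for (t in thr) {
      left <- xv <= t
      yl <- y[left]; yr <- y[!left]
      sse <- sum((yl - mean(yl))^2) + sum((yr - mean(yr))^2)
      if (sse < best_sse - 1e-12) {  # strict improvement: earliest j, t wins ties
        best_sse <- sse
        best <- list(j = j, t = t)
      }
    }
  }
  if (is.null(best)) {
    return(list(leaf = TRUE, value = mean(y), n = length(y), depth = depth))
  }
  left <- X[, best$j] <= best$t
  list(leaf = FALSE, feature = best$j, threshold = best$t, depth = depth,
       left = grow_tree(X[left, , drop = FALSE], y[left], depth + 1, max_depth),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], depth + 1, max_depth))
}

tree_depth <- function(node) {
  if (node$leaf) return(node$depth)
  max(tree_depth(node$left), tree_depth(node$right))
}

predict_tree <- function(node, x) {
  while (!node$leaf) {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  node$value
}

#' Small fully connected regression network
#'
#' A 5-input multilayer perceptron with hidden ReLU layers of 64, 32,
#' 16 and 5 neurons and a linear output neuron, trained on squared
#' error by minibatch SGD with early stopping: training halts once the
#' validation loss has not improved for `spec$patience` epochs (default
#' 15) and the best-validation weights are restored.
#'
#' @inheritParams fit_mlr
#' @export
fit_nn <- function(X, y, spec = model_spec("NN")) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  if (ncol(X) != 5) {
    stop(sprintf("the network loads exactly 5 features, got %d", ncol(X)),
         call. = FALSE)
  }
  std <- if (spec$standardize) std_fit(X) else list(center = rep(0, 5),
                                                    scale = rep(1, 5))
  Xs <- std_apply(X, std)
  n <- nrow(Xs)
  old_seed <- set_local_seed(spec$seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  n_val <- max(1, round(spec$val_frac * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  sizes <- c(ncol(Xs), spec$nn_layers, 1)
  W <- lapply(seq_len(length(sizes) - 1), function(i) {
    matrix(stats::rnorm(sizes[i] * sizes[i + 1], sd = sqrt(2 / sizes[i])),
           sizes[i], sizes[i + 1])
  })
  B <- lapply(sizes[-1], function(s) rep(0, s))
  forward <- function(Xb) {
    A <- list(Xb)
    for (l in seq_along(W)) {
      Z <- A[[l]] %*% W[[l]] + matrix(B[[l]], nrow(A[[l]]), length(B[[l]]),
                                      byrow = TRUE)
      A[[l + 1]] <- if (l < length(W)) pmax(Z, 0) else Z
    }
    A
  }
  mse <- function(idx) {
    pred <- forward(Xs[idx, , drop = FALSE])[[length(W) + 1]][, 1]
    mean((y[idx] - pred)^2)
  }
  bs <- if (is.null(spec$batch_size)) length(tr_idx) else
    min(spec$batch_size, length(tr_idx))
  best_val <- Inf; best <- list(W = W, B = B); wait <- 0
  tr_curve <- val_curve <- numeric(0)
  converged <- FALSE
  for (epoch in seq_len(spec$epochs)) {
    lr_t <- spec$lr / (1 + spec$lr_decay * (epoch - 1))
    idx <- sample(tr_idx)
    for (start in seq(1, length(idx), by = bs)) {
      batch <- idx[start:min(start + bs - 1, length(idx))]
      A <- forward(Xs[batch, , drop = FALSE])
      nb <- length(batch)
      delta <- (A[[length(W) + 1]] - y[batch]) * (2 / nb)  # dL/dZ_out
      for (l in rev(seq_along(W))) {
        gW <- crossprod(A[[l]], delta)
        gB <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
        W[[l]] <- W[[l]] - lr_t * gW
        B[[l]] <- B[[l]] - lr_t * gB
      }
    }
    tr_curve <- c(tr_curve, mse(tr_idx))
    v <- mse(val_idx)
    val_curve <- c(val_curve, v)
    if (v < best_val - 1e-12) {
      best_val <- v; best <- list(W = W, B = B); wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= spec$patience) { converged <- TRUE; break }
    }
  }
  new_fit("NN", spec, std, W = best$W, B = best$B,
          loss_curve = tr_curve, val_curve = val_curve,
          converged = converged, stopped_epoch = length(tr_curve),
          val_idx = val_idx, features = colnames(X))
}

#' Logistic classification by SGD
#'
#' Minimizes the cross-entropy `-(y log p + (1 - y) log(1 - p))` with
#' `p = sigmoid(X w + beta)` by minibatch SGD. Predicted probabilities
#' are clipped to `(1e-12, 1 - 1e-12)` so the loss stays finite.
#'
#' @param labels binary (0/1) vector.
#' @inheritParams fit_mlr
#' @export
fit_logistic <- function(X, labels, spec = model_spec("LOGISTIC", alpha = 0)) {
  X <- as_feature_matrix(X)
  y <- as.numeric(labels)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  if (length(unique(y)) < 2) stop("need both classes present", call. = FALSE)
  std <- if (spec$standardize) std_fit(X) else list(center = rep(0, ncol(X)),
                                                    scale = rep(1, ncol(X)))
  Xs <- std_apply(X, std)
  sigmoid <- function(z) 1 / (1 + exp(-z))
  clip_p <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  grad_fn <- function(w, b, Xb, yb) {
    p <- sigmoid((Xb %*% w + b)[, 1])
    d <- p - yb
    list(gw = crossprod(Xb, d)[, 1] / length(yb), gb = mean(d))
  }
  loss_fn <- function(w, b) {
    p <- clip_p(sigmoid((Xs %*% w + b)[, 1]))
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  opt <- sgd_optimize(Xs, y, spec, grad_fn, loss_fn)
  new_fit("LOGISTIC", spec, std, w = opt$w, beta = opt$b,
          loss_curve = opt$loss_curve, features = colnames(X))
}

#' Predict from a fitted chromox model
#'
#' @param object a `chromox_fit`.
#' @param newdata feature matrix or data frame.
#' @param type for logistic fits, `"response"` (probability, default)
#'   or `"class"` (0/1 at the 0.5 threshold).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.chromox_fit <- function(object, newdata, type = "response", ...) {
  X <- as_feature_matrix(newdata)
  if (object$kind == "PR") {
    X <- cbind(X, X^2)
  }
  if (object$kind == "DTR") {
    return(apply(X, 1, function(x) predict_tree(object$tree, x)))
  }
  Xs <- if (!is.null(object$std)) std_apply(X, object$std) else X
  if (object$kind == "NN") {
    A <- Xs
    W <- object$W; B <- object$B
    for (l in seq_along(W)) {
      Z <- A %*% W[[l]] + matrix(B[[l]], nrow(A), length(B[[l]]), byrow = TRUE)
      A <- if (l < length(W)) pmax(Z, 0) else Z
    }
    return(A[, 1])
  }
  eta <- (Xs %*% object$w + object$beta)[, 1]
  if (object$kind == "LOGISTIC") {
    p <- 1 / (1 + exp(-eta))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    return(if (identical(type, "class")) as.numeric(p > 0.5) else p)
  }
  eta
}

#' Deterministic K-fold partition
#'
#' Shuffles indices under the given seed and deals them into K folds
#' whose sizes differ by at most one; every sample lands in exactly one
#' validation fold.
#'
#' @param n number of samples (`n >= K`).
#' @param K number of folds (default 10).
#' @param seed RNG seed.
#' @return List of K integer vectors of validation indices.
#' @export
kfold_indices <- function(n, K = 10, seed = 20240101) {
  if (n < K) stop("need at least K samples", call. = FALSE)
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  idx <- sample.int(n)
  folds <- split(idx, rep_len(seq_len(K), n))
  names(folds) <- NULL
  lapply(folds, unname)
}

#' K-fold cross-validation of a model fit
#'
#' Fits on K-1 folds and scores RMSE on the held-out fold; feature
#' standardization happens inside each training fold (the fit functions
#' learn and store their own scaling), so no information leaks into the
#' validation folds.
#'
#' @param X,y data.
#' @param fit_fun function `(X, y) -> chromox_fit`.
#' @param K number of folds.
#' @param seed seed for the fold partition.
#' @return A list with `cv_rmse` (length-K numeric) and `folds`.
#' @export
kfold_cv <- function(X, y, fit_fun, K = 10, seed = 20240101) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  folds <- kfold_indices(length(y), K, seed)
  cv_rmse <- vapply(folds, function(val) {
    fit <- fit_fun(X[-val, , drop = FALSE], y[-val])
    pred <- stats::predict(fit, X[val, , drop = FALSE])
    sqrt(mean((y[val] - pred)^2))
  }, numeric(1))
  list(cv_rmse = unname(cv_rmse), folds = folds)
}
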