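#' Melanin index from narrow-band reflectance
#'
#' Standard narrow-band melanin index from skin reflectance at 655 nm:
#' `M = 100 * log10(1 / R)`. Monotone decreasing in reflectance; 0 for
#' a perfect reflector.
#'
#' @param reflectance_655 reflectance fraction in `(0, 1]`.
#' @return Melanin index M.
#' @export
melanin_index <- function(reflectance_655) {
  if (any(!is.finite(reflectance_655) | reflectance_655 <= 0 |
          reflectance_655 > 1)) {
    stop("reflectance must lie in (0, 1]", call. = FALSE)
  }
  100 * log10(1 / reflectance_655)
}

#' Baseline skin tone from repeated site measurements
#'
#' The standard baseline is the average of the inner-arm measurements
#' over both arms (2 sites x 3 replicates); outer-arm data are retained
#' in the input but do not enter the baseline.
#'
#' @param measurements data frame with columns `site` (one of
#'   `"inner_left"`, `"inner_right"`, `"outer_left"`, `"outer_right"`),
#'   `L`, `a`, `b`, `reflectance`.
#' @return A list with `L`, `a`, `b`, `reflectance`, and `M` (melanin
#'   index of the baseline reflectance).
#' @export
baseline_skin_tone <- function(measurements) {
  stopifnot(all(c("site", "L", "a", "b", "reflectance") %in% names(measurements)))
  inner <- measurements[measurements$site %in% c("inner_left", "inner_right"), ]
  missing <- setdiff(c("inner_left", "inner_right"), unique(inner$site))
  if (length(missing) > 0) {
    stop("missing inner-arm site(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  refl <- mean(inner$reflectance)
  list(L = mean(inner$L), a = mean(inner$a), b = mean(inner$b),
       reflectance = refl, M = melanin_index(refl))
}

#' Melanin-lightness relation across a cohort
#'
#' Fits the sigmoidal link between melanin index M and inverse
#' lightness 1/L* (4-parameter logistic) together with its linear
#' approximation, reporting R-squared for both. Over a mid-range
#' cohort the linear approximation is close, which is what licenses the
#' linear melanin terms in the correction models.
#'
#' @param cohort data frame with columns `m_index` and `L`.
#' @return A list with `logistic` (parameters `A`, `B`, `x0`, `s` and
#'   `r_squared`) and `linear` (`slope`, `intercept`, `r_squared`).
#' @export
fit_melanin_tone_relation <- function(cohort) {
  stopifnot(all(c("m_index", "L") %in% names(cohort)))
  if (nrow(cohort) < 10) stop("need at least 10 subjects", call. = FALSE)
  if (stats::sd(cohort$L) == 0) stop("degenerate cohort: single tone", call. = FALSE)
  x <- 1 / cohort$L
  M <- cohort$m_index
  lin <- stats::lm(M ~ x)
  start <- list(A = min(M), B = max(M), x0 = stats::median(x),
                s = stats::sd(x) / 2)
  nls_fit <- minpack.lm::nlsLM(
    M ~ A + (B - A) / (1 + exp(-(x - x0) / s)),
    start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  pred <- stats::predict(nls_fit)
  sst <- sum((M - mean(M))^2)
  list(
    logistic = c(as.list(stats::coef(nls_fit)),
                 r_squared = 1 - sum((M - pred)^2) / sst),
    linear = list(slope = unname(stats::coef(lin)[2]),
                  intercept = unname(stats::coef(lin)[1]),
                  r_squared = summary(lin)$r.squared)
  )
}

# Lasso-regularized fit followed by an OLS refit on the selected
# support. The L1 stage performs feature selection; the refit removes
# the shrinkage bias so that generating weights are recovered exactly
# in the noise-free limit. Returns raw-scale weights.
fit_linear_lasso_refit <- function(X, y, alpha = 0.1, spec = NULL) {
  X <- as_feature_matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(spec)) {
    spec <- model_spec("MLR", alpha = alpha, lr = 0.05, epochs = 300,
                       batch_size = 32)
  }
  lasso <- fit_mlr(X, y, spec)
  selected <- which(abs(lasso$w) > spec$alpha / 2)
  if (length(selected) == 0) selected <- seq_len(ncol(X))
  df <- data.frame(y = y, X[, selected, drop = FALSE])
  ols <- stats::lm(y ~ ., data = df)
  w <- stats::setNames(rep(0, ncol(X)), colnames(X))
  w[selected] <- stats::coef(ols)[-1]
  w[is.na(w)] <- 0
  list(beta = unname(stats::coef(ols)[1]), w = w,
       selected = colnames(X)[selected], lasso = lasso)
}

#' Skin-tone correction of the pulse-oximeter index
#'
#' Models the gold-standard SpO2 as a linear function of the oximeter
#' index, the standard (spectrophotometer) skin tone L*, a*, b* and the
#' melanin index, removing the melanin-dependent underestimation of the
#' oximeter. Fitting uses the Lasso-regularized machinery for feature
#' selection with an OLS refit on the selected support.
#'
#' @param cohort data frame with columns `oximeter_index`, `L`, `a`,
#'   `b`, `m_index`, `gold_spo2`.
#' @param alpha L1 degree, default 0.1.
#' @param spec optional [model_spec()] override for the selection stage.
#' @return An object of class `chromox_correction`: `beta`, `w` (named
#'   raw-scale weights), `selected`, `features`.
#' @export
fit_oximeter_correction <- function(cohort, alpha = 0.1, spec = NULL) {
  feats <- c("oximeter_index", "L", "a", "b", "m_index")
  stopifnot(all(c(feats, "gold_spo2") %in% names(cohort)))
  if (any(!is.finite(cohort$gold_spo2))) {
    stop("missing gold-standard SpO2", call. = FALSE)
  }
  fit <- fit_linear_lasso_refit(as.matrix(cohort[feats]), cohort$gold_spo2,
                                alpha = alpha, spec = spec)
  structure(c(fit, list(features = feats, response = "gold_spo2")),
            class = "chromox_correction")
}

#' @rdname fit_oximeter_correction
#' @param record data frame of subjects to correct (same feature columns).
#' @param weights a fitted `chromox_correction`.
#' @return `apply_oximeter_correction`: corrected SpO2, clipped to
#'   `[0, 100]`.
#' @export
apply_oximeter_correction <- function(record, weights) {
  stopifnot(inherits(weights, "chromox_correction"))
  X <- as.matrix(record[weights$features])
  pred <- weights$beta + as.numeric(X %*% weights$w)
  pmin(pmax(pred, 0), 100)
}

#' Correction of smartphone-imaged skin tone
#'
#' Four linear models mapping the imaged tone (`L_s`, `a_s`, `b_s`,
#' `G_s`, `B_s`) plus the camera setting (log2 ISO, or the brightness V
#' fallback when ISO is unavailable) onto the spectrophotometer tone
#' L*, a*, b* and the melanin index, enabling tone measurement without
#' specialized instruments.
#'
#' @param cohort data frame with imaged-tone columns and standard-tone
#'   columns `L`, `a`, `b`, `m_index`; camera setting from `iso` or
#'   fallback column `v`.
#' @param alpha L1 degree.
#' @param spec optional [model_spec()] override.
#' @return An object of class `chromox_color_correction`: a list of
#'   four `chromox_correction`-style fits (one per target) plus the
#'   feature names used.
#' @export
fit_color_correction <- function(cohort, alpha = 0.1, spec = NULL) {
  imaged <- c("L_s", "a_s", "b_s", "G_s", "B_s")
  stopifnot(all(imaged %in% names(cohort)))
  if (nrow(cohort) < 8) stop("underdetermined: need more subjects", call. = FALSE)
  cam <- if ("iso" %in% names(cohort)) {
    log2(cohort$iso / 200)
  } else if ("v" %in% names(cohort)) {
    cohort$v
  } else {
    stop("neither ISO nor brightness V present", call. = FALSE)
  }
  X <- cbind(as.matrix(cohort[imaged]), camera = cam)
  targets <- c("L", "a", "b", "m_index")
  fits <- lapply(targets, function(tg) {
    fit_linear_lasso_refit(X, cohort[[tg]], alpha = alpha, spec = spec)
  })
  names(fits) <- targets
  structure(list(fits = fits, features = imaged, targets = targets),
            class = "chromox_color_correction")
}

#' @rdname fit_color_correction
#' @param record data frame of subjects to correct.
#' @param weights a fitted `chromox_color_correction`.
#' @return `apply_color_correction`: data frame with corrected `L`,
#'   `a`, `b`, `m_index`.
#' @export
apply_color_correction <- function(record, weights) {
  stopifnot(inherits(weights, "chromox_color_correction"))
  cam <- if ("iso" %in% names(record)) {
    log2(record$iso / 200)
  } else if ("v" %in% names(record)) {
    record$v
  } else {
    stop("neither ISO nor brightness V present", call. = FALSE)
  }
  X <- cbind(as.matrix(record[weights$features]), camera = cam)
  out <- lapply(weights$fits, function(f) f$beta + as.numeric(X %*% f$w))
  as.data.frame(out)
}

# Noise-based training: an exactly-20% seeded subset of training rows
# receives additive Gaussian feature noise (sd = noise_scale * feature
# sd) before the linear fit; the injection mask is recorded.
noise_based_fit <- function(X, y, noise_frac = 0.2, noise_scale = 0.1,
                            alpha = 0.1, seed = 20240101, spec = NULL) {
  X <- as_feature_matrix(X)
  n <- nrow(X)
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  n_noise <- round(noise_frac * n)
  mask <- sort(sample.int(n, n_noise))
  Xn <- X
  if (n_noise > 0) {
    sds <- apply(X, 2, stats::sd)
    noise <- matrix(stats::rnorm(n_noise * ncol(X)), n_noise, ncol(X))
    Xn[mask, ] <- X[mask, ] + sweep(noise, 2, noise_scale * sds, "*")
  }
  fit <- fit_linear_lasso_refit(Xn, y, alpha = alpha, spec = spec)
  c(fit, list(noise_mask = mask, noise_frac = noise_frac,
              noise_scale = noise_scale, seed = seed))
}

#' App SpO2 model over corrected features
#'
#' The clinical-model stage of the correction workflow: a linear model
#' of the cross-dimensional lip color features together with the
#' corrected skin tone, trained against the corrected oximeter index as
#' reference. Training uses the noise-based strategy (noise injected
#' into exactly 20 % of training rows) shared with the pCO2 model.
#'
#' @param cohort data frame containing the lip feature columns and the
#'   corrected-feature columns.
#' @param reference numeric reference values (the corrected oximeter
#'   index).
#' @param lip_features names of the lip feature columns.
#' @param tone_features names of corrected tone columns to include.
#' @param split optional `c(n_train, n_test)`; when given, rows are
#'   split at random (seeded) into exactly these sizes and the model is
#'   fitted on the training rows only.
#' @param seed RNG seed for the split and the noise injection.
#' @param alpha,noise_frac,noise_scale training-time settings.
#' @return An object of class `chromox_spo2_model` with the linear fit,
#'   the noise mask, and the split indices (if any).
#' @export
fit_app_spo2_model <- function(cohort, reference,
                               lip_features = c("lip_h", "lip_s", "lip_v",
                                                "lip_a", "lip_b"),
                               tone_features = character(0),
                               split = NULL, seed = 20240101,
                               alpha = 0.1, noise_frac = 0.2,
                               noise_scale = 0.1) {
  feats <- c(lip_features, tone_features)
  stopifnot(all(feats %in% names(cohort)), length(reference) == nrow(cohort))
  train_idx <- seq_len(nrow(cohort))
  test_idx <- integer(0)
  if (!is.null(split)) {
    stopifnot(length(split) == 2, sum(split) == nrow(cohort))
    old_seed <- set_local_seed(seed)
    train_idx <- sort(sample.int(nrow(cohort), split[1]))
    test_idx <- setdiff(seq_len(nrow(cohort)), train_idx)
    restore_seed(old_seed)
  }
  X <- as.matrix(cohort[train_idx, feats])
  fit <- noise_based_fit(X, reference[train_idx], noise_frac = noise_frac,
                         noise_scale = noise_scale, alpha = alpha,
                         seed = seed)
  structure(c(fit, list(features = feats, train_idx = train_idx,
                        test_idx = test_idx)),
            class = "chromox_spo2_model")
}

#' @rdname fit_app_spo2_model
#' @param record data frame of subjects to predict.
#' @param model a fitted `chromox_spo2_model`.
#' @return `predict_spo2`: predicted SpO2, clipped to `[0, 100]`.
#' @export
predict_spo2 <- function(record, model) {
  stopifnot(inherits(model, "chromox_spo2_model"))
  X <- as.matrix(record[model$features])
  pmin(pmax(model$beta + as.numeric(X %*% model$w), 0), 100)
}

#' pCO2 measurement model
#'
#' Linear model `pCO2 = f . T + beta1` over the cross-dimensional lip
#' and skin tone features, trained with the noise-based strategy: an
#' exactly-20 % seeded subset of training rows receives additive
#' Gaussian feature noise so the model learns patterns robust to
#' environmental variation.
#'
#' @param cohort data frame with the feature columns and `pco2_gold`.
#' @param features names of the feature columns T1..Tn.
#' @inheritParams fit_app_spo2_model
#' @return An object of class `chromox_pco2_model`.
#' @export
fit_pco2_model <- function(cohort, features = c("t1", "t2", "t3"),
                           seed = 20240101, alpha = 0.1,
                           noise_frac = 0.2, noise_scale = 0.1) {
  stopifnot(all(features %in% names(cohort)))
  if (!"pco2_gold" %in% names(cohort) || all(!is.finite(cohort$pco2_gold))) {
    stop("no pCO2 labels in cohort", call. = FALSE)
  }
  X <- as.matrix(cohort[features])
  fit <- noise_based_fit(X, cohort$pco2_gold, noise_frac = noise_frac,
                         noise_scale = noise_scale, alpha = alpha, seed = seed)
  structure(c(fit, list(features = features)), class = "chromox_pco2_model")
}

#' @rdname fit_pco2_model
#' @param record data frame of subjects to predict.
#' @param model a fitted `chromox_pco2_model`.
#' @return `predict_pco2`: predicted pCO2 in mmHg, clipped to
#'   `[10, 100]`.
#' @export
predict_pco2 <- function(record, model) {
  stopifnot(inherits(model, "chromox_pco2_model"))
  X <- as.matrix(record[model$features])
  pmin(pmax(model$beta + as.numeric(X %*% model$w), 10), 100)
}

#' Hypoxemia and SpO2-band classification
#'
#' `classify_hypoxemia` labels SpO2 at or below the 95 % cutoff as
#' `"low"`; `classify_band` assigns the three monitoring bands
#' `"<95"`, `"[95,97)"`, `"[97,100]"`.
#'
#' @param spo2 SpO2 values in `[0, 100]`.
#' @return Character vector of labels.
#' @export
classify_hypoxemia <- function(spo2) {
  if (any(!is.finite(spo2) | spo2 < 0 | spo2 > 100)) {
    stop("SpO2 must lie in [0, 100]", call. = FALSE)
  }
  ifelse(spo2 <= 95, "low", "normal")
}

#' @rdname classify_hypoxemia
#' @export
classify_band <- function(spo2) {
  if (any(!is.finite(spo2) | spo2 < 0 | spo2 > 100)) {
    stop("SpO2 must lie in [0, 100]", call. = FALSE)
  }
  ifelse(spo2 < 95, "<95", ifelse(spo2 < 97, "[95,97)", "[97,100]"))
}

#' Bland-Altman agreement analysis
#'
#' Bias and 95 % limits of agreement between two measurement methods.
#' Sign convention: first argument (method under test) minus second
#' (reference).
#'
#' @param x,y equal-length numeric vectors (`n >= 2`).
#' @return A list with `bias`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  stopifnot(length(x) >= 2)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' @rdname bland_altman
#' @return `error_metrics`: a list with `mean_abs_error` and `rmse`.
#' @export
error_metrics <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  d <- x - y
  list(mean_abs_error = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' Full interconnected correction pipeline
#'
#' Runs the whole correction workflow on a cohort: (1) the oximeter
#' correction is fitted against the gold standard; (2) the color
#' correction maps imaged tones onto standard tones; (3) the app SpO2
#' model is fitted on lip features plus corrected tone, with the
#' corrected oximeter index as reference. Agreement metrics against the
#' gold standard are reported overall and per Fitzpatrick stratum.
#'
#' @param cohort a cohort data frame (see [generate_cohort()]).
#' @param seed seed for the noise-based training stage.
#' @param alpha L1 degree for all fits.
#' @return A list with the three fitted models, per-subject corrected
#'   values (`corrected_oximeter`, `app_spo2`), and `metrics` (overall
#'   and per-stratum mean absolute errors).
#' @export
oximetry_pipeline <- function(cohort, seed = 20240101, alpha = 0.1) {
  oxi <- fit_oximeter_correction(cohort, alpha = alpha)
  corrected_oxi <- apply_oximeter_correction(cohort, oxi)
  col <- fit_color_correction(cohort, alpha = alpha)
  tone_hat <- apply_color_correction(cohort, col)
  aug <- cbind(cohort, tone_L = tone_hat$L, tone_a = tone_hat$a,
               tone_b = tone_hat$b, tone_m = tone_hat$m_index)
  app <- fit_app_spo2_model(aug, corrected_oxi,
                            tone_features = c("tone_L", "tone_a", "tone_b",
                                              "tone_m"),
                            seed = seed, alpha = alpha)
  app_pred <- predict_spo2(aug, app)
  per_stratum <- function(v) {
    vapply(split(seq_len(nrow(cohort)), cohort$fitzpatrick),
           function(i) mean(abs(v[i] - cohort$gold_spo2[i])), numeric(1))
  }
  metrics <- list(
    raw_oximeter_mae = mean(abs(cohort$oximeter_index - cohort$gold_spo2)),
    corrected_oximeter_mae = mean(abs(corrected_oxi - cohort$gold_spo2)),
    app_mae = mean(abs(app_pred - cohort$gold_spo2)),
    raw_oximeter_mae_by_stratum = per_stratum(cohort$oximeter_index),
    corrected_oximeter_mae_by_stratum = per_stratum(corrected_oxi),
    app_mae_by_stratum = per_stratum(app_pred)
  )
  list(oximeter_correction = oxi, color_correction = col, app_model = app,
       corrected_oximeter = corrected_oxi, app_spo2 = app_pred,
       metrics = metrics)
}
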