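test_that("melanin index follows the narrow-band log formula", {
  expect_equal(melanin_index(1.0), 0)
  expect_equal(melanin_index(0.1), 100)
  r <- seq(0.05, 1, length.out = 50)
  expect_true(all(diff(melanin_index(r)) < 0))
  expect_error(melanin_index(0), "\\(0, 1\\]")
  expect_error(melanin_index(1.2), "\\(0, 1\\]")
})

test_that("baseline skin tone averages inner arms and ignores outer arms", {
  m <- data.frame(
    site = rep(c("inner_left", "inner_right", "outer_left", "outer_right"),
               each = 3),
    L = c(rep(60, 3), rep(62, 3), rep(50, 6)),
    a = rep(12, 12), b = rep(15, 12),
    reflectance = rep(0.3, 12)
  )
  base <- baseline_skin_tone(m)
  expect_equal(base$L, 61)
  expect_equal(base$M, melanin_index(0.3))
  expect_error(baseline_skin_tone(m[m$site != "inner_left", ]),
               "inner_left")
})

test_that("melanin-tone relation recovers a known logistic link", {
  # noiseless cohort on the generating curve
  L <- seq(35, 66, length.out = 40)
  x <- 1 / L
  M <- 25 + 75 / (1 + exp(-(x - 0.021) / 0.004))
  rel <- fit_melanin_tone_relation(data.frame(m_index = M, L = L))
  expect_equal(rel$logistic$A, 25, tolerance = 1e-3)
  expect_equal(rel$logistic$B, 100, tolerance = 1e-3)
  expect_equal(rel$logistic$x0, 0.021, tolerance = 1e-5)
  expect_gt(rel$logistic$r_squared, 0.9999)
  # mid-range cohort: linear approximation is close
  co <- generate_cohort(120, seed = 31)
  rel2 <- fit_melanin_tone_relation(co)
  expect_gt(rel2$linear$r_squared, 0.95)
  expect_error(fit_melanin_tone_relation(data.frame(m_index = M[1:12],
                                                    L = rep(50, 12))),
               "single tone")
})

test_that("oximeter correction recovers generating weights without noise", {
  co <- generate_cohort(200, seed = 7, noise_f = 0, noise_img = 0,
                        noise_lip = 0)
  truth <- attr(co, "truth")
  fit <- fit_oximeter_correction(co)
  expect_lt(abs(fit$w["oximeter_index"] - 1), 0.01)
  expect_lt(abs(fit$w["m_index"] - truth$oximeter_bias) /
              truth$oximeter_bias, 0.01)
})

test_that("oximeter correction reduces the melanin-dependent error", {
  co <- generate_cohort(200, seed = 8)
  fit <- fit_oximeter_correction(co)
  corrected <- apply_oximeter_correction(co, fit)
  raw_mae <- mean(abs(co$oximeter_index - co$gold_spo2))
  cor_mae <- mean(abs(corrected - co$gold_spo2))
  expect_lt(cor_mae, raw_mae)
  expect_true(all(corrected >= 0 & corrected <= 100))
})

test_that("a bias-free cohort yields an identity-like correction", {
  co <- generate_cohort(200, seed = 9, oximeter_bias = 0, noise_f = 0.01)
  fit <- fit_oximeter_correction(co)
  expect_equal(unname(fit$w["oximeter_index"]), 1, tolerance = 0.01)
  corrected <- apply_oximeter_correction(co, fit)
  expect_lt(mean(abs(corrected - co$oximeter_index)), 0.1)
})

test_that("color correction inverts a known affine tone distortion", {
  co <- generate_cohort(150, seed = 10, noise_img = 0)
  fit <- fit_color_correction(co)
  hat <- apply_color_correction(co, fit)
  expect_lt(mean(abs(hat$L - co$L)), 0.1)
  expect_lt(mean(abs(hat$a - co$a)), 0.1)
  expect_lt(mean(abs(hat$b - co$b)), 0.1)
  expect_error(fit_color_correction(co[1, ]), "underdetermined")
  no_cam <- co[setdiff(names(co), "iso")]
  expect_error(fit_color_correction(no_cam), "neither ISO nor brightness")
})

test_that("app SpO2 model predicts the reference within noise scale", {
  co <- generate_cohort(97, seed = 12)
  # the generating model is linear in the lip features plus skin tone
  fit <- fit_app_spo2_model(co, co$gold_spo2, tone_features = "L")
  pred <- predict_spo2(co, fit)
  rmse <- sqrt(mean((pred - co$gold_spo2)^2))
  expect_lt(rmse, 0.6)
  # negative control: permuted labels leave only the outcome spread
  set.seed(13)
  fitp <- fit_app_spo2_model(co, sample(co$gold_spo2))
  predp <- predict_spo2(co, fitp)
  expect_gt(sqrt(mean((predp - co$gold_spo2)^2)), 0.5 * sd(co$gold_spo2))
})

test_that("the configured 58/39 train/test split is honored exactly", {
  co <- generate_cohort(97, seed = 14)
  fit <- fit_app_spo2_model(co, co$gold_spo2, split = c(58, 39))
  expect_length(fit$train_idx, 58)
  expect_length(fit$test_idx, 39)
  expect_equal(sort(c(fit$train_idx, fit$test_idx)), 1:97)
})

test_that("pCO2 model recovers generating weights and books its noise mask", {
  co <- generate_cohort(200, seed = 15)
  truth <- attr(co, "truth")$pco2_cf
  fit <- fit_pco2_model(co)
  expect_length(fit$noise_mask, round(0.2 * 200))
  expect_lt(max(abs(fit$w - truth$f) / abs(truth$f)), 0.05)
  # prediction equals the linear form by hand
  rec <- co[3, ]
  by_hand <- fit$beta + sum(fit$w * unlist(rec[c("t1", "t2", "t3")]))
  expect_equal(predict_pco2(rec, fit), min(max(by_hand, 10), 100),
               tolerance = 1e-10)
  no_pco2 <- co
  no_pco2$pco2_gold <- NA_real_
  expect_error(fit_pco2_model(no_pco2), "pCO2 labels")
})

test_that("noise-based training is reproducible bit for bit", {
  co <- generate_cohort(100, seed = 16)
  f1 <- fit_pco2_model(co, seed = 33)
  f2 <- fit_pco2_model(co, seed = 33)
  expect_identical(f1$w, f2$w)
  expect_identical(f1$noise_mask, f2$noise_mask)
})

test_that("SpO2 and pCO2 model residuals are uncorrelated", {
  co <- generate_cohort(1000, seed = 17)
  spo2_fit <- fit_app_spo2_model(co, co$gold_spo2)
  pco2_fit <- fit_pco2_model(co)
  r1 <- predict_spo2(co, spo2_fit) - co$gold_spo2
  r2 <- predict_pco2(co, pco2_fit) - co$pco2_gold
  expect_lt(abs(cor(r1, r2)), 0.1)
})

test_that("hypoxemia and band classification follow the stated cutoffs", {
  expect_equal(classify_hypoxemia(95.0), "low")
  expect_equal(classify_hypoxemia(95.1), "normal")
  expect_equal(classify_band(95.1), "[95,97)")
  expect_equal(classify_band(94.9), "<95")
  expect_equal(classify_band(97), "[97,100]")
  expect_equal(classify_band(100), "[97,100]")
  expect_error(classify_hypoxemia(105), "\\[0, 100\\]")
  # monotone: lowering SpO2 never flips low -> normal
  s <- seq(100, 0, by = -0.5)
  lab <- classify_hypoxemia(s)
  expect_false(any(lab == "normal" & cumsum(lab == "low") > 0))
})

test_that("Bland-Altman statistics match closed forms", {
  x <- c(1, 2, 3, 4)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  ba1 <- bland_altman(x + 1, x)
  expect_equal(ba1$bias, 1)
  expect_equal(ba1$loa_low, 1)
  em <- error_metrics(x + 1, x)
  expect_equal(em$mean_abs_error, 1)
  expect_equal(em$rmse, 1)
  expect_error(bland_altman(1:3, 1:4), "length mismatch")
  # Monte-Carlo agreement with the normal closed form
  set.seed(18)
  d <- rnorm(1e5, 0.5, 1)
  ba <- bland_altman(d, rep(0, 1e5))
  expect_equal(ba$bias, 0.5, tolerance = 0.02)
  expect_equal(ba$loa_low, 0.5 - 1.96, tolerance = 0.05)
  expect_equal(ba$loa_high, 0.5 + 1.96, tolerance = 0.05)
})

test_that("the full correction pipeline improves accuracy in every stratum", {
  co <- generate_cohort(200, seed = 19)
  pipe <- oximetry_pipeline(co)
  m <- pipe$metrics
  expect_lt(m$corrected_oximeter_mae, m$raw_oximeter_mae)
  expect_lt(m$app_mae, m$raw_oximeter_mae)
  expect_true(all(m$corrected_oximeter_mae_by_stratum <
                    m$raw_oximeter_mae_by_stratum))
  # app beats the raw oximeter wherever melanin bias is material
  biased <- c("IV", "V", "VI")
  expect_true(all(m$app_mae_by_stratum[biased] <
                    m$raw_oximeter_mae_by_stratum[biased]))
  # inclusivity: app accuracy is comparable across all strata
  expect_lt(max(m$app_mae_by_stratum), 2.5 * min(m$app_mae_by_stratum))
})
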