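#' Beer-Lambert dye reflectance map
#'
#' Maps analyte concentration to groove reflectance, channel by
#' channel: `reflectance = base * 10^(-k * conc)`. The default is a
#' green-absorbing (red-family) dye whose extinction difference between
#' the green and red channels keeps the SCQP signal close to linear
#' over 0-100 ug/mL, the regime in which saturation-derived
#' quantification is valid.
#'
#' @param base clean-groove RGB reflectance in `[0, 1]`.
#' @param k per-channel extinction coefficients per (ug/mL).
#' @return Function `conc -> length-3 RGB reflectance`.
#' @export
dye_map <- function(base = c(0.92, 0.90, 0.85),
                    k = c(0.0002, 0.0015, 0.0010)) {
  stopifnot(length(base) == 3, length(k) == 3, all(base > 0 & base <= 1))
  function(conc) {
    if (any(conc < 0)) stop("concentration must be >= 0", call. = FALSE)
    base * 10^(-k * conc)
  }
}

#' Render a 6x6 colorimetric chip reflectance scene
#'
#' Builds the noiseless scene: square dye-filled grooves on a dark
#' (black-background) plate, one concentration per groove. Ground truth
#' (groove centers, boxes, concentrations) travels with the scene so
#' detection and quantification can be scored exactly.
#'
#' @param conc 6x6 concentration matrix (row-major layout on the chip),
#'   or a length-6 vector of per-row concentrations.
#' @param dye a [dye_map()].
#' @param cell_px cell pitch in pixels.
#' @param margin_px plate margin around the grid.
#' @param groove_frac linear fraction of the cell occupied by a groove.
#' @param background plate reflectance.
#' @param rotation_deg in-plane rotation of the groove lattice about the
#'   image center (small angles; squares stay axis-aligned).
#' @return A list of class `chromox_scene`: `scene` (H x W x 3 array in
#'   `[0, 1]`), `centers` (36 x 2 matrix of x/y pixel centers, 0-based,
#'   row-major), `conc` (6x6 matrix), `cell_px`, `groove_px`.
#' @export
chip_scene <- function(conc, dye = dye_map(), cell_px = 56, margin_px = 16,
                       groove_frac = 0.7, background = 0.06,
                       rotation_deg = 0) {
  if (is.vector(conc) && length(conc) == 6) {
    conc <- matrix(rep(conc, each = 6), 6, 6, byrow = TRUE)
  }
  stopifnot(is.matrix(conc), all(dim(conc) == c(6, 6)))
  if (any(conc < 0)) stop("concentration must be >= 0", call. = FALSE)
  side <- 6 * cell_px + 2 * margin_px
  scene <- array(background, c(side, side, 3))
  g <- round(groove_frac * cell_px)
  half <- g %/% 2
  theta <- rotation_deg * pi / 180
  ctr <- (side - 1) / 2
  centers <- matrix(0, 36, 2, dimnames = list(NULL, c("x", "y")))
  i <- 1
  for (row in 1:6) {
    for (col in 1:6) {
      cx0 <- margin_px + (col - 0.5) * cell_px
      cy0 <- margin_px + (row - 0.5) * cell_px
      # rotate lattice about image center
      cx <- ctr + cos(theta) * (cx0 - ctr) - sin(theta) * (cy0 - ctr)
      cy <- ctr + sin(theta) * (cx0 - ctr) + cos(theta) * (cy0 - ctr)
      centers[i, ] <- c(cx, cy)
      rgb <- dye(conc[row, col])
      ys <- max(1, round(cy) - half):min(side, round(cy) + half)
      xs <- max(1, round(cx) - half):min(side, round(cx) + half)
      for (ch in 1:3) scene[ys, xs, ch] <- rgb[ch]
      i <- i + 1
    }
  }
  structure(list(scene = scene, centers = centers, conc = conc,
                 cell_px = cell_px, groove_px = g, background = background),
            class = "chromox_scene")
}

#' Smartphone camera forward model
#'
#' Collects every interference the calibration stack must undo:
#' a smooth multiplicative illumination field, exponential shooting-
#' distance attenuation (`tau^(-delta_d / 5)`, the same family the
#' distance calibration inverts, so closure is exact in the noise-free
#' limit), an optional auto-exposure gain driven by mean scene
#' luminance, white-balance gains, additive Gaussian sensor noise, and
#' power-law gamma encoding.
#'
#' @param gamma gamma correction factor (encode exponent `1/gamma`).
#' @param illumination `"flat"`, `"gradient"` (left-right ramp),
#'   `"corner"` (radial falloff toward one corner), or a function
#'   `(h, w) -> matrix` of multiplicative illumination in `[0.3, 1]`.
#' @param illum_range range of the built-in illumination fields.
#' @param distance_cm,ref_distance_cm shooting and reference distances.
#' @param tau attenuation base per 5 cm.
#' @param auto_exposure apply gain `0.5 / mean-luminance` clipped to
#'   `[0.5, 2]` (emulates a phone's automatic exposure).
#' @param noise_sigma additive Gaussian sd per channel (linear domain).
#' @param wb_gains length-3 channel gains applied by the camera.
#' @return An object of class `chromox_camera`.
#' @export
camera_model <- function(gamma = 2.2, illumination = "flat",
                         illum_range = c(0.55, 1),
                         distance_cm = 20, ref_distance_cm = 20, tau = 1.1,
                         auto_exposure = FALSE, noise_sigma = 0,
                         wb_gains = c(1, 1, 1)) {
  stopifnot(gamma > 0, tau > 0, noise_sigma >= 0, length(wb_gains) == 3)
  structure(as.list(environment()), class = "chromox_camera")
}

illumination_field <- function(camera, h, w) {
  il <- camera$illumination
  if (is.function(il)) return(il(h, w))
  lo <- camera$illum_range[1]; hi <- camera$illum_range[2]
  switch(il,
    flat = matrix(hi, h, w),
    gradient = matrix(rep(seq(lo, hi, length.out = w), each = h), h, w),
    corner = {
      d <- sqrt(outer(seq_len(h)^2, seq_len(w)^2, "+"))
      lo + (hi - lo) * (1 - d / max(d))
    },
    stop("unknown illumination field: ", il, call. = FALSE)
  )
}

#' Render a scene through the camera model
#'
#' `pixel = gamma_encode(clip(scene * illumination * tau^(-dd/5) *
#' auto_gain * wb + noise))` with `dd = distance - reference distance`.
#' The returned image is continuous-valued in `[0, 1]`; quantization to
#' 8 bits only happens when writing to disk, so calibration closure can
#' be validated below the quantization floor.
#'
#' @param scene a `chromox_scene` or an H x W x 3 array in `[0, 1]`.
#' @param camera a [camera_model()].
#' @param seed RNG seed for the sensor noise (required when
#'   `noise_sigma > 0`).
#' @return A list with `image` (encoded array) and `meta` (distance,
#'   gain, gamma, tau, white balance, noise level and seed -- everything
#'   needed to invert the render).
#' @export
render_chip <- function(scene, camera = camera_model(), seed = NULL) {
  arr <- if (inherits(scene, "chromox_scene")) scene$scene else scene
  check_rgb_array(arr)
  h <- dim(arr)[1]; w <- dim(arr)[2]
  illum <- illumination_field(camera, h, w)
  dd <- camera$distance_cm - camera$ref_distance_cm
  att <- camera$tau^(-dd / 5)
  lin <- arr
  for (ch in 1:3) lin[, , ch] <- arr[, , ch] * illum * att
  gain <- 1
  if (isTRUE(camera$auto_exposure)) {
    luma <- 0.299 * lin[, , 1] + 0.587 * lin[, , 2] + 0.114 * lin[, , 3]
    gain <- min(max(0.5 / mean(luma), 0.5), 2)
  }
  for (ch in 1:3) lin[, , ch] <- lin[, , ch] * gain * camera$wb_gains[ch]
  if (camera$noise_sigma > 0) {
    if (is.null(seed)) stop("seed required when noise_sigma > 0", call. = FALSE)
    old_seed <- set_local_seed(seed)
    on.exit(restore_seed(old_seed), add = TRUE)
    lin <- lin + array(stats::rnorm(length(lin), sd = camera$noise_sigma),
                       dim(lin))
  }
  lin <- pmin(pmax(lin, 0), 1)
  img <- gamma_encode(lin, camera$gamma, max_value = 1)
  meta <- list(distance_cm = camera$distance_cm,
               ref_distance_cm = camera$ref_distance_cm,
               delta_distance = dd, tau = camera$tau, gamma = camera$gamma,
               auto_gain = gain, wb_gains = camera$wb_gains,
               noise_sigma = camera$noise_sigma, seed = seed)
  list(image = img, meta = meta)
}

#' Generate a synthetic subject cohort
#'
#' Emulates the clinical study design on which the correction system is
#' validated: subjects span Fitzpatrick types II-VI; the melanin index
#' M follows a 4-parameter logistic link to the inverse lightness
#' 1/L*; narrow-band reflectance is `10^(-M/100)`; gold-standard SpO2
#' is a mixture of a cyanotic (low) and a noncyanotic (normal)
#' component; the pulse-oximeter index underestimates in proportion to
#' melanin (`F = A - bias * (M - M_ref) + noise`); imaged skin tones
#' are an affine distortion of the spectrophotometer tones plus an
#' ISO-dependent shift; and the lip color features carry a linear SpO2
#' signal with a mild skin-tone confound. Every generating coefficient
#' is stored in the `"truth"` attribute for parameter-recovery tests.
#'
#' @param n number of subjects.
#' @param seed RNG seed (generation is bit-reproducible).
#' @param fitz_probs sampling weights over Fitzpatrick types II-VI.
#' @param oximeter_bias oximeter underestimation per melanin unit
#'   (percent SpO2 per M unit).
#' @param ccgd_prob probability of the cyanotic (low-SpO2) component.
#' @param noise_f oximeter noise sd (percent).
#' @param noise_lip lip-feature noise sd.
#' @param noise_img imaged-tone noise sd.
#' @param stratified allocate subjects round-robin over strata instead
#'   of sampling (guarantees every stratum is populated).
#' @return A data frame, one row per subject, with attribute `"truth"`.
#' @export
generate_cohort <- function(n = 200, seed = 20240101,
                            fitz_probs = rep(0.2, 5),
                            oximeter_bias = 0.08, ccgd_prob = 8 / 26,
                            noise_f = 0.2, noise_lip = 0.3, noise_img = 1.0,
                            stratified = FALSE) {
  stopifnot(n >= 1, length(fitz_probs) == 5, all(fitz_probs >= 0))
  if (sum(fitz_probs) <= 0) stop("invalid Fitzpatrick distribution", call. = FALSE)
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  strata <- c("II", "III", "IV", "V", "VI")
  L_mean <- c(II = 66, III = 60, IV = 53, V = 45, VI = 36)
  fitz <- if (stratified) {
    rep_len(strata, n)
  } else {
    sample(strata, n, replace = TRUE, prob = fitz_probs / sum(fitz_probs))
  }
  # melanin-lightness logistic link (M vs 1/L*)
  logi <- list(A = 25, B = 100, x0 = 0.021, s = 0.004)
  L <- stats::rnorm(n, L_mean[fitz], 2)
  a <- 10 + 0.05 * (65 - L) + stats::rnorm(n, 0, 1)
  b <- 14 + 0.08 * (65 - L) + stats::rnorm(n, 0, 1.5)
  x <- 1 / L
  M <- logi$A + (logi$B - logi$A) / (1 + exp(-(x - logi$x0) / logi$s)) +
    stats::rnorm(n, 0, 1.5)
  M <- pmin(pmax(M, 1), 99)
  reflectance_655 <- 10^(-M / 100)
  cyanotic <- stats::runif(n) < ccgd_prob
  A_gold <- ifelse(cyanotic,
                   pmin(pmax(stats::rnorm(n, 82, 4), 65), 92),
                   pmin(pmax(stats::rnorm(n, 97, 1.2), 90), 100))
  M_ref <- 35
  F_oxi <- A_gold - oximeter_bias * (M - M_ref) + stats::rnorm(n, 0, noise_f)
  F_oxi <- pmin(pmax(F_oxi, 0), 100)
  iso <- sample(c(100, 125, 160, 200, 320, 400), n, replace = TRUE)
  isoz <- log2(iso / 200)
  # imaged tones: affine distortion + ISO shift
  img_cf <- list(L = c(0.92, -3, 1.5), a = c(1.05, 1.0, 0.5),
                 b = c(0.95, 2.0, -0.8))
  L_s <- img_cf$L[1] * L + img_cf$L[2] + img_cf$L[3] * isoz +
    stats::rnorm(n, 0, noise_img)
  a_s <- img_cf$a[1] * a + img_cf$a[2] + img_cf$a[3] * isoz +
    stats::rnorm(n, 0, noise_img / 2)
  b_s <- img_cf$b[1] * b + img_cf$b[2] + img_cf$b[3] * isoz +
    stats::rnorm(n, 0, noise_img / 2)
  G_s <- 120 + 1.8 * (L - 50) - 0.6 * (a - 12) + stats::rnorm(n, 0, noise_img)
  B_s <- 105 + 1.6 * (L - 50) - 0.9 * (b - 15) + stats::rnorm(n, 0, noise_img)
  # lip color features: linear SpO2 signal with a skin-tone confound
  lip_cf <- list(h = c(10, 0.15), s = c(20, 0.45, -0.10),
                 v = c(35, 0.25, 0.12), a = c(8, 0.28), b = c(30, -0.20))
  lip_h <- lip_cf$h[1] + lip_cf$h[2] * (100 - A_gold) + stats::rnorm(n, 0, noise_lip)
  lip_s <- lip_cf$s[1] + lip_cf$s[2] * A_gold + lip_cf$s[3] * (65 - L) +
    stats::rnorm(n, 0, noise_lip)
  lip_v <- lip_cf$v[1] + lip_cf$v[2] * A_gold + lip_cf$v[3] * (L - 50) +
    stats::rnorm(n, 0, noise_lip)
  lip_a <- lip_cf$a[1] + lip_cf$a[2] * A_gold + stats::rnorm(n, 0, noise_lip)
  lip_b <- lip_cf$b[1] + lip_cf$b[2] * A_gold + stats::rnorm(n, 0, noise_lip)
  # pCO2 block, independent of the SpO2 signal: the app-extracted
  # features T1..T3 carry independent variation (t3 with a skin-tone
  # component) and pCO2 is their linear combination plus noise, so the
  # generating weights f are identifiable.
  pco2_cf <- list(f = c(t1 = 0.8, t2 = -0.5, t3 = 0.6), beta1 = 33)
  t1 <- stats::rnorm(n, 10, 5)
  t2 <- stats::rnorm(n, 20, 5)
  t3 <- stats::rnorm(n, 15, 4) + 0.1 * (65 - L)
  pco2 <- pco2_cf$beta1 + pco2_cf$f[1] * t1 + pco2_cf$f[2] * t2 +
    pco2_cf$f[3] * t3 + stats::rnorm(n, 0, noise_lip)
  pco2 <- pmin(pmax(pco2, 15), 80)
  cohort <- data.frame(
    subject = seq_len(n), fitzpatrick = fitz, cyanotic = cyanotic,
    L = L, a = a, b = b, m_index = M, reflectance_655 = reflectance_655,
    gold_spo2 = A_gold, oximeter_index = F_oxi, iso = iso,
    L_s = L_s, a_s = a_s, b_s = b_s, G_s = G_s, B_s = B_s,
    lip_h = lip_h, lip_s = lip_s, lip_v = lip_v, lip_a = lip_a, lip_b = lip_b,
    pco2_gold = pco2, t1 = t1, t2 = t2, t3 = t3,
    stringsAsFactors = FALSE
  )
  attr(cohort, "truth") <- list(
    logistic = logi, oximeter_bias = oximeter_bias, M_ref = M_ref,
    img_cf = img_cf, lip_cf = lip_cf, pco2_cf = pco2_cf,
    L_mean = L_mean, noise = c(f = noise_f, lip = noise_lip, img = noise_img)
  )
  cohort
}

#' Generate the worked fixture bundle
#'
#' One deterministic bundle used throughout the examples and the
#' validation suite: a chip concentration series (0, 5, 10, 20, 50,
#' 100 ug/mL per row) rendered under 2 illumination fields x 2
#' shooting distances plus a clean reference render, and a 30-subject
#' cohort spanning Fitzpatrick II-VI with at least 4 subjects per
#' stratum. Images are written as 8-bit PNG with a JSON sidecar carrying
#' the render metadata and ground truth; re-running with the same seed
#' reproduces the bundle byte for byte.
#'
#' @param dir output directory (created if missing).
#' @param seed RNG seed.
#' @return Invisibly, a manifest list: scene, file paths, cohort.
#' @export
generate_worked_fixture <- function(dir, seed = 20240101) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conc <- c(0, 5, 10, 20, 50, 100)
  scene <- chip_scene(conc)
  conditions <- expand.grid(illum = c("gradient", "corner"),
                            distance = c(20, 25), stringsAsFactors = FALSE)
  files <- character(0)
  for (i in seq_len(nrow(conditions))) {
    cam <- camera_model(illumination = conditions$illum[i],
                        distance_cm = conditions$distance[i],
                        ref_distance_cm = 20)
    r <- render_chip(scene, cam, seed = seed + i)
    stem <- file.path(dir, sprintf("chip_%s_d%d", conditions$illum[i],
                                   conditions$distance[i]))
    png::writePNG(r$image, paste0(stem, ".png"))
    sidecar <- c(r$meta, list(conc_rows = conc,
                              centers = unname(scene$centers)))
    jsonlite::write_json(sidecar, paste0(stem, ".json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, paste0(stem, ".png"), paste0(stem, ".json"))
  }
  ref <- render_chip(scene, camera_model(illumination = "flat"))
  png::writePNG(ref$image, file.path(dir, "chip_reference.png"))
  files <- c(files, file.path(dir, "chip_reference.png"))
  cohort <- generate_cohort(30, seed = seed, stratified = TRUE)
  cohort_path <- file.path(dir, "cohort.csv")
  utils::write.csv(cohort, cohort_path, row.names = FALSE)
  files <- c(files, cohort_path)
  invisible(list(scene = scene, conditions = conditions, files = files,
                 cohort = cohort, seed = seed))
}
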