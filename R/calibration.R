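#' Normalized 2-D Gaussian kernel
#'
#' Surround function for the multiscale evenness algorithm. The kernel
#' is truncated at `radius` pixels and renormalized so its entries sum
#' to exactly one (normalization constant `C = 1 / sum(F)`).
#'
#' @param sigma Gaussian scale in pixels, `> 0`.
#' @param radius truncation radius in pixels; defaults to `ceiling(3 * sigma)`.
#' @return A `(2 * radius + 1)` square matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  x <- seq(-radius, radius)
  k2 <- outer(x, x, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  k2 / sum(k2)
}

# 1-D Gaussian taps, normalized
gaussian_taps <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian convolution with reflective boundary handling.
# Reflection requires radius <= dim - 1; smaller images are an error.
gaussian_blur <- function(I, sigma, radius = ceiling(3 * sigma)) {
  if (radius > min(dim(I)) - 1) {
    stop(sprintf(
      "image (%d x %d) smaller than kernel support (radius %d)",
      nrow(I), ncol(I), radius
    ), call. = FALSE)
  }
  taps <- gaussian_taps(sigma, radius)
  conv_rows <- function(M) {
    n <- nrow(M)
    pad_idx <- c(rev(seq_len(radius) + 1L), seq_len(n), n - seq_len(radius))
    P <- M[pad_idx, , drop = FALSE]
    out <- matrix(0, n, ncol(M))
    for (k in seq_along(taps)) {
      out <- out + taps[k] * P[(k - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(I))))
}

#' Multiscale Gaussian surround of a V matrix
#'
#' Averages Gaussian-filtered copies of the brightness matrix over the
#' configured scales (equal weights), the multiscale-retinex surround
#' restricted to the V channel. Reflective padding avoids the edge
#' darkening that zero padding would cause.
#'
#' @param I brightness (V) matrix with entries in `[0, 1]`.
#' @param sigmas Gaussian scales in pixels; the defaults
#'   `c(20, 72, 250)` balance dynamic-range compression against feature
#'   detail for full-resolution phone images and should be scaled down
#'   proportionally for smaller frames.
#' @return A list with `I` (input), `L` (surround matrix), `L_avg`
#'   (scalar mean of `L`).
#' @export
multiscale_surround <- function(I, sigmas = c(20, 72, 250)) {
  stopifnot(is.matrix(I), all(sigmas > 0))
  if (any(I < 0 | I > 1)) stop("V matrix entries must lie in [0, 1]", call. = FALSE)
  L <- Reduce(`+`, lapply(sigmas, function(s) gaussian_blur(I, s))) / length(sigmas)
  L <- pmin(pmax(L, 0), 1)
  list(I = I, L = L, L_avg = mean(L))
}

#' Illumination-evenness calibration of an RGB image
#'
#' Deviation equalization of the V channel: the multiscale surround `L`
#' estimates the illumination field and the calibrated brightness is
#' `N = clip(I + k * (L_avg - L), 0, 1)` with calibration index
#' `k = 1 - mu`. `mu = 1` leaves the image untouched; `mu = 0` applies
#' full flattening toward the mean surround. Only V is modified: each
#' pixel's channels are rescaled by `N/V`, which leaves hue and
#' saturation exactly unchanged (ratios of channels are preserved), and
#' the image is re-encoded from the equalized values.
#'
#' @param img RGB array (`H x W x 3`) with values in `[0, 1]`.
#' @param mu calibration control in `[0, 1]`; smaller values calibrate
#'   more strongly.
#' @param sigmas surround scales, see [multiscale_surround()].
#' @return Calibrated RGB array, same shape as `img`.
#' @export
evenness_calibrate <- function(img, mu, sigmas = c(20, 72, 250)) {
  check_rgb_array(img)
  if (!is.finite(mu) || mu < 0 || mu > 1) stop("mu must lie in [0, 1]", call. = FALSE)
  V <- pmax(img[, , 1], img[, , 2], img[, , 3])
  ms <- multiscale_surround(V, sigmas)
  k <- 1 - mu
  N <- pmin(pmax(V + k * (ms$L_avg - ms$L), 0), 1)
  scale <- ifelse(V > 0, N / V, 0)
  out <- img
  for (ch in 1:3) out[, , ch] <- img[, , ch] * scale
  # V = 0 pixels are black; equalization can only brighten them to gray
  black <- V == 0
  if (any(black)) for (ch in 1:3) out[, , ch][black] <- N[black]
  out
}

#' Gamma decoding and encoding of 8-bit channel values
#'
#' The camera applies a power-law (gamma) encoding between the linear
#' sensor signal `D` and the displayed value `G`:
#' `G = max * (D/max)^(1/gamma)`. `gamma_decode` inverts the encoding to
#' recover linear-light values; `gamma_encode` re-applies it. The two
#' are exact inverses.
#'
#' @param x channel values in `[0, max_value]` (vector, matrix or array).
#' @param gamma gamma correction factor; phone displays sit in
#'   `[2.0, 2.2]`, default 2.2.
#' @param max_value full-scale channel value, default 255.
#' @return Transformed values on the same scale.
#' @export
gamma_decode <- function(x, gamma = 2.2, max_value = 255) {
  stopifnot(gamma > 0)
  max_value * (x / max_value)^gamma
}

#' @rdname gamma_decode
#' @export
gamma_encode <- function(x, gamma = 2.2, max_value = 255) {
  stopifnot(gamma > 0)
  max_value * (x / max_value)^(1 / gamma)
}

#' Shooting-distance calibration of linear channel values
#'
#' Normalizes an image taken at a different shooting distance onto the
#' reference distance through an exponential distance model: the
#' gamma-decoded (linear) channels of the second image are scaled by
#' `tau^(delta_distance / 5)`, i.e. by the amendment factor `tau` per
#' 5 cm step, then clipped and re-encoded. With `tau = 1.1` a 5 cm
#' retreat is compensated by a 10 % linear gain.
#'
#' @param D2 linear-light channel values (from [gamma_decode()]) of the
#'   image to calibrate, in `[0, max_value]`.
#' @param delta_distance distance difference in cm between the image and
#'   the reference image (positive: farther away). The reference step is
#'   5 cm.
#' @param tau amendment factor per 5 cm, `> 0`; default 1.1.
#' @param gamma gamma used for re-encoding; default 2.2.
#' @param max_value full-scale channel value, default 255.
#' @return A list with `C_D2` (calibrated linear channels) and `N`
#'   (gamma re-encoded output channels).
#' @export
distance_calibrate <- function(D2, delta_distance, tau = 1.1, gamma = 2.2,
                               max_value = 255) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  C_D2 <- pmin(pmax(D2 * tau^(delta_distance / 5), 0), max_value)
  list(C_D2 = C_D2, N = gamma_encode(C_D2, gamma, max_value))
}

#' Mean absolute residual between reference and calibrated channels
#'
#' The agreement metric used to tune the amendment factor: mean
#' `|D1 - C_D2|` over all channels, where `D1` holds the linear channels
#' of the reference-distance image.
#'
#' @param D1 linear channels of the reference image.
#' @param C_D2 calibrated linear channels of the second image.
#' @return Scalar mean absolute residual.
#' @export
distance_residual <- function(D1, C_D2) {
  stopifnot(length(D1) == length(C_D2))
  mean(abs(D1 - C_D2))
}

#' Grey-world white balance
#'
#' Stabilizes the raw color of an image by scaling each channel so that
#' the channel means equal the grey-world mean (the mean over all three
#' channel means).
#'
#' @param img RGB array (`H x W x 3`) in `[0, 1]`.
#' @return A list with `image` (balanced array, clipped to `[0, 1]`) and
#'   `gains` (per-channel multipliers).
#' @export
white_balance_grayworld <- function(img) {
  check_rgb_array(img)
  means <- vapply(1:3, function(ch) mean(img[, , ch]), numeric(1))
  if (any(means == 0)) stop("channel mean is zero; cannot white balance", call. = FALSE)
  gains <- mean(means) / means
  out <- img
  for (ch in 1:3) out[, , ch] <- pmin(pmax(img[, , ch] * gains[ch], 0), 1)
  list(image = out, gains = gains)
}

check_rgb_array <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  }
  if (any(img < 0 | img > 1)) stop("RGB array values must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}
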