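#' Convert 8-bit RGB to HSV
#'
#' Hexcone HSV with the scale conventions used throughout chromox:
#' hue in degrees `[0, 360)`, saturation and value as percentages
#' `[0, 100]`. Achromatic pixels (`max(r,g,b) == min(r,g,b)`) get hue 0
#' and are flagged.
#'
#' @param r,g,b integer channel intensities in `[0, 255]`, recycled to a
#'   common length.
#' @return A data frame with columns `h`, `s`, `v` and logical
#'   `achromatic`.
#' @examples
#' rgb_to_hsv(200, 100, 50)  # h = 20, s = 75, v = 78.43
#' @export
rgb_to_hsv <- function(r, g, b) {
  check_rgb(r, g, b)
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  data.frame(
    h = hsv["h", ] * 360,
    s = hsv["s", ] * 100,
    v = hsv["v", ] * 100,
    achromatic = hsv["s", ] == 0,
    row.names = NULL
  )
}

#' Convert HSV back to 8-bit RGB
#'
#' Inverse of [rgb_to_hsv()]; channels are rounded to integers, so a
#' round trip is exact to within one 8-bit unit per channel.
#'
#' @param h hue in degrees `[0, 360)`.
#' @param s,v saturation and value as percentages `[0, 100]`.
#' @return A data frame with integer columns `r`, `g`, `b`.
#' @export
hsv_to_rgb <- function(h, s, v) {
  stopifnot(all(is.finite(h)), all(s >= 0 & s <= 100), all(v >= 0 & v <= 100))
  cols <- grDevices::hsv(h %% 360 / 360, s / 100, v / 100)
  m <- grDevices::col2rgb(cols)
  data.frame(r = m["red", ], g = m["green", ], b = m["blue", ], row.names = NULL)
}

# sRGB (IEC 61966-2-1) -> XYZ, D65 white, 2 degree observer
.srgb_to_xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

.d65_white <- c(0.95047, 1.00000, 1.08883)

#' Convert 8-bit RGB to CIELAB
#'
#' Device-independent skin-tone coordinates: sRGB primaries, D65 white
#' point, 2 degree standard observer. One fixed convention is used so
#' that values are comparable across the package; cameras that deviate
#' from sRGB are handled upstream by the colour-correction models, not
#' here.
#'
#' @inheritParams rgb_to_hsv
#' @return A data frame with columns `L` (0-100), `a`, `b`.
#' @examples
#' rgb_to_lab(255, 0, 0)  # L ~ 53.24, a ~ 80.09, b ~ 67.20
#' @export
rgb_to_lab <- function(r, g, b) {
  check_rgb(r, g, b)
  rgb01 <- rbind(r, g, b) / 255
  lin <- ifelse(rgb01 <= 0.04045, rgb01 / 12.92, ((rgb01 + 0.055) / 1.055)^2.4)
  xyz <- .srgb_to_xyz %*% lin
  f <- function(t) {
    delta <- 6 / 29
    ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
  }
  fx <- f(xyz[1, ] / .d65_white[1])
  fy <- f(xyz[2, ] / .d65_white[2])
  fz <- f(xyz[3, ] / .d65_white[3])
  data.frame(
    L = 116 * fy - 16,
    a = 500 * (fx - fy),
    b = 200 * (fy - fz),
    row.names = NULL
  )
}

#' Convert 8-bit RGB to grayscale intensity
#'
#' Luma as the ITU-R BT.601 weighted average of the channels, on the
#' `[0, 1]` scale.
#'
#' @inheritParams rgb_to_hsv
#' @return Numeric vector of intensities in `[0, 1]`.
#' @export
rgb_to_gray <- function(r, g, b) {
  check_rgb(r, g, b)
  (0.299 * r + 0.587 * g + 0.114 * b) / 255
}

#' Strongly correlated quantitative parameter (SCQP)
#'
#' The G/V channel ratio. Because both G and V (the maximum channel)
#' scale identically with illumination intensity, the ratio is invariant
#' to multiplicative illumination changes, which is what makes its
#' complement `signal = 1 - G/V` a robust quantifier for dyes that
#' absorb in the green. When G is the minimum channel, `signal` equals
#' the HSV saturation exactly; elsewhere it extends saturation-based
#' quantification over the full concentration range.
#'
#' @inheritParams rgb_to_hsv
#' @return A data frame with columns `value` (G/V, in `[0, 1]`) and
#'   `signal` (`1 - value`, monotone with concentration for red-family
#'   analytes).
#' @examples
#' compute_scqp(200, 100, 50)  # value 0.5, signal 0.5
#' @export
compute_scqp <- function(r, g, b) {
  check_rgb(r, g, b)
  n <- max(length(r), length(g), length(b))
  r <- rep_len(r, n); g <- rep_len(g, n); b <- rep_len(b, n)
  mx <- pmax(r, g, b)
  if (any(mx == 0)) {
    stop("SCQP is undefined for achromatic black pixels (V = 0)", call. = FALSE)
  }
  value <- g / mx
  data.frame(value = value, signal = 1 - value, row.names = NULL)
}

check_rgb <- function(r, g, b) {
  vals <- c(r, g, b)
  if (!all(is.finite(vals)) || any(vals < 0) || any(vals > 255)) {
    stop("RGB channels must be finite values in [0, 255]", call. = FALSE)
  }
  invisible(TRUE)
}
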