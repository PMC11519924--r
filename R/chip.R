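#' Detect the 6x6 groove grid on a chip image
#'
#' Segmentation recipe: grayscale, Sobel gradient magnitude, Otsu
#' threshold, morphological closing, hull filling, connected components,
#' then a k-means grid fit on the component centroids (6 row clusters on
#' y, 6 column clusters on x). Returns sampling boxes covering the inner
#' 60 % of each detected groove, in row-major order, with 0-based
#' half-open pixel coordinates.
#'
#' @param img RGB array (`H x W x 3`) in `[0, 1]`.
#' @param rows,cols expected grid dimensions.
#' @param min_area_frac components smaller than this fraction of the
#'   median component area are discarded as specks.
#' @param inner_frac linear fraction of the groove covered by the box.
#' @return An object of class `chromox_roigrid`: `boxes` (data frame
#'   with `row`, `col`, `x0`, `y0`, `x1`, `y1`), `centers`, `rows`,
#'   `cols`.
#' @export
detect_grid <- function(img, rows = 6, cols = 6, min_area_frac = 0.2,
                        inner_frac = 0.6) {
  check_rgb_array(img)
  gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(gray, kx, boundary = "replicate")
  gy <- EBImage::filter2(gray, t(kx), boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) {
    stop("grid detection failed: 0 of 36 cells found (blank image)",
         call. = FALSE)
  }
  mag <- mag / max(mag)
  thr <- EBImage::otsu(EBImage::Image(mag), range = c(0, 1))
  bw <- EBImage::closing(mag > thr, EBImage::makeBrush(5, "disc"))
  filled <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(filled)
  lab <- as.matrix(EBImage::imageData(lab))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_frac * stats::median(areas[areas > 0]))
  if (length(keep) != rows * cols) {
    stop(sprintf("grid detection failed: %d of %d cells found",
                 length(keep), rows * cols), call. = FALSE)
  }
  cy <- vapply(keep, function(k) mean(row(lab)[lab == k]), numeric(1))
  cx <- vapply(keep, function(k) mean(col(lab)[lab == k]), numeric(1))
  side <- sqrt(areas[keep])
  row_id <- grid_cluster(cy, rows)
  col_id <- grid_cluster(cx, cols)
  if (any(table(row_id, col_id) != 1)) {
    stop("grid detection failed: centroids do not form a full grid",
         call. = FALSE)
  }
  half <- floor(inner_frac * stats::median(side) / 2)
  ord <- order(row_id, col_id)
  boxes <- data.frame(
    row = row_id[ord], col = col_id[ord],
    x0 = round(cx[ord]) - half - 1, y0 = round(cy[ord]) - half - 1,
    x1 = round(cx[ord]) + half, y1 = round(cy[ord]) + half
  )
  structure(list(rows = rows, cols = cols, boxes = boxes,
                 centers = cbind(x = cx[ord] - 1, y = cy[ord] - 1)),
            class = "chromox_roigrid")
}

# 1-D k-means with deterministic quantile initialization; returns
# cluster labels renumbered in ascending center order.
grid_cluster <- function(v, k) {
  centers <- stats::quantile(v, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  km <- suppressWarnings(stats::kmeans(v, centers = matrix(centers)))
  rank <- order(order(km$centers[, 1]))
  rank[km$cluster]
}

#' Extract an artifact-filtered groove signal
#'
#' Filters shadows and light-reflection spots on the per-pixel
#' brightness V in two stages: (1) a symmetric rank-based percentile
#' trim drops the lowest and highest 5 % of pixels (so a uniform box
#' rejects approximately the nominal 10 %); (2) a robust deviation
#' screen rejects surviving pixels whose V departs from the surviving
#' median by more than `3 * max(MAD, 0.005)`, which removes glare
#' plateaus and shadow bands too wide for the tails alone. The mean
#' color of the survivors is reported together with its SCQP.
#'
#' @param img RGB array in `[0, 1]`.
#' @param box one row of a `chromox_roigrid` `boxes` frame (or any list
#'   with `x0`, `y0`, `x1`, `y1`, 0-based half-open).
#' @param trim lower/upper V percentiles, default `c(0.05, 0.95)`.
#' @param min_pixels minimum surviving pixel count.
#' @return An object of class `chromox_groove`: mean `r`, `g`, `b` (8-bit
#'   scale), `scqp`, `signal`, `pixel_count`, `rejected_fraction`.
#' @export
extract_signal <- function(img, box, trim = c(0.05, 0.95), min_pixels = 25) {
  check_rgb_array(img)
  ys <- (box$y0 + 1):box$y1
  xs <- (box$x0 + 1):box$x1
  if (min(ys) < 1 || min(xs) < 1 || max(ys) > dim(img)[1] ||
      max(xs) > dim(img)[2]) {
    stop("box lies outside the image", call. = FALSE)
  }
  r <- as.vector(img[ys, xs, 1]); g <- as.vector(img[ys, xs, 2])
  b <- as.vector(img[ys, xs, 3])
  v <- pmax(r, g, b)
  n <- length(v)
  ord <- order(v)
  lo <- floor(trim[1] * n)
  hi <- floor((1 - trim[2]) * n)
  mid <- ord[(lo + 1):(n - hi)]
  med <- stats::median(v[mid])
  thr <- 3 * max(stats::mad(v[mid]), 0.005)
  keep_idx <- mid[abs(v[mid] - med) <= thr]
  keep <- logical(n)
  keep[keep_idx] <- TRUE
  rejected <- 1 - mean(keep)
  if (rejected > 0.8) stop("unusable groove: >80% of pixels rejected", call. = FALSE)
  if (sum(keep) < min_pixels) {
    stop(sprintf("unusable groove: only %d usable pixels (< %d)",
                 sum(keep), min_pixels), call. = FALSE)
  }
  mr <- mean(r[keep]) * 255; mg <- mean(g[keep]) * 255; mb <- mean(b[keep]) * 255
  sc <- compute_scqp(mr, mg, mb)
  structure(list(r = mr, g = mg, b = mb,
                 scqp = sc$value, signal = sc$signal,
                 pixel_count = sum(keep), rejected_fraction = rejected),
            class = "chromox_groove")
}

#' Fit a concentration calibration curve
#'
#' Ordinary least squares of concentration on the SCQP signal of the
#' standard grooves.
#'
#' @param concentration numeric vector of standard concentrations
#'   (at least 3 distinct values).
#' @param signal matching SCQP signals (or any scalar quantifier).
#' @return An object of class `chromox_curve`: `slope`, `intercept`,
#'   `r_squared`, `signal_range`, `conc_range`.
#' @export
fit_calibration_curve <- function(concentration, signal) {
  stopifnot(length(concentration) == length(signal))
  if (length(unique(concentration)) < 3) {
    stop("need at least 3 distinct standard concentrations", call. = FALSE)
  }
  if (stats::sd(signal) == 0) {
    stop("degenerate standards: all signals equal", call. = FALSE)
  }
  fit <- stats::lm(concentration ~ signal)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((concentration - mean(concentration))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 signal_range = range(signal),
                 conc_range = range(concentration)),
            class = "chromox_curve")
}

#' Quantify a sample groove against a calibration curve
#'
#' @param signal SCQP signal of the sample groove (scalar or vector),
#'   or a `chromox_groove`.
#' @param curve a `chromox_curve`.
#' @return A data frame with `concentration` and logical `extrapolated`
#'   (signal outside the calibration range).
#' @export
quantify <- function(signal, curve) {
  stopifnot(inherits(curve, "chromox_curve"))
  if (inherits(signal, "chromox_groove")) signal <- signal$signal
  data.frame(
    concentration = curve$intercept + curve$slope * signal,
    extrapolated = signal < curve$signal_range[1] |
      signal > curve$signal_range[2]
  )
}

#' Analyze a chip image end to end
#'
#' Detects the grid, extracts all 36 artifact-filtered groove signals
#' and, when standards are supplied, fits the calibration curve and
#' quantifies every groove.
#'
#' @param img RGB array in `[0, 1]`.
#' @param standards optional data frame with columns `row`, `col`,
#'   `concentration` naming the standard grooves.
#' @param grid optional pre-detected `chromox_roigrid`.
#' @param ... passed to [extract_signal()].
#' @return A data frame with one row per groove (`row`, `col`, `r`,
#'   `g`, `b`, `scqp`, `signal`, `pixel_count`, `rejected_fraction`,
#'   and `concentration`/`extrapolated` when standards are given); the
#'   fitted curve is attached as attribute `"curve"`.
#' @export
analyze_chip <- function(img, standards = NULL, grid = NULL, ...) {
  if (is.null(grid)) grid <- detect_grid(img)
  sig <- lapply(seq_len(nrow(grid$boxes)), function(i) {
    s <- extract_signal(img, grid$boxes[i, ], ...)
    data.frame(row = grid$boxes$row[i], col = grid$boxes$col[i],
               r = s$r, g = s$g, b = s$b, scqp = s$scqp, signal = s$signal,
               pixel_count = s$pixel_count,
               rejected_fraction = s$rejected_fraction)
  })
  out <- do.call(rbind, sig)
  if (!is.null(standards)) {
    stopifnot(all(c("row", "col", "concentration") %in% names(standards)))
    m <- merge(out, standards, by = c("row", "col"))
    curve <- fit_calibration_curve(m$concentration, m$signal)
    q <- quantify(out$signal, curve)
    out$concentration <- q$concentration
    out$extrapolated <- q$extrapolated
    attr(out, "curve") <- curve
  }
  out
}
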