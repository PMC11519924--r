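#' Read an 8-bit RGB image
#'
#' PNG is read natively; TIFF and JPEG fall back to EBImage. Grayscale
#' images are expanded to three channels and alpha is dropped.
#'
#' @param path image file path.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    arr <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(arr)) == 3) aperm(arr, c(2, 1, 3)) else t(arr)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  pmin(pmax(img, 0), 1)
}

#' Write an image as 8-bit PNG
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param path output path (`.png`).
#' @export
write_image <- function(img, path) {
  check_rgb_array(img)
  png::writePNG(img, path)
  invisible(path)
}
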