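#' Calibrated grayscale image
#'
#' A 2-D grid of intensities in physical units: `pixels` is a numeric matrix
#' with values typically in \[0, 1\] and `px_size_um` is the edge length of a
#' pixel in micrometers. All morphometric quantities downstream are reported
#' in micrometers, so the calibration is carried with the image rather than
#' supplied again at every step.
#'
#' @param pixels Numeric matrix of finite intensities, at least 2 x 2.
#' @param px_size_um Micrometers per pixel, > 0.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, px_size_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.",
          class = "airspace_error_validation")
  }
  if (nrow(pixels) < 2 || ncol(pixels) < 2) {
    abort("Image must be at least 2 x 2 pixels.",
          class = "airspace_error_validation")
  }
  if (!all(is.finite(pixels))) {
    abort("Image intensities must all be finite.",
          class = "airspace_error_validation")
  }
  stop_if_not_scalar_number(px_size_um, "px_size_um", min = 0,
                            strict_min = TRUE)
  structure(list(pixels = pixels, px_size_um = px_size_um),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.3g um/px, range [%.3f, %.3f]\n",
              nrow(x$pixels), ncol(x$pixels), x$px_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read an image file with a physical calibration
#'
#' Reads an 8- or 16-bit PNG or TIFF, rescales integer intensities to
#' \[0, 1\], converts RGB(A) input to luminance via [to_grayscale()], and
#' attaches the pixel size. Calibration is always supplied by the caller:
#' embedded file metadata is ignored because histology exports rarely carry
#' reliable physical units.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param px_size_um Micrometers per pixel, > 0.
#' @return A [calibrated_image()].
#' @export
read_calibrated_image <- function(path, px_size_um) {
  stop_if_not_scalar_number(px_size_um, "px_size_um", min = 0,
                            strict_min = TRUE)
  if (!is.character(path) || length(path) != 1L || !file.exists(path) ||
      file.size(path) == 0) {
    abort(sprintf("Cannot read image file '%s'.", as.character(path)[1]),
          class = "airspace_error_io")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("Unsupported image format '%s' for '%s'.", ext, path),
          class = "airspace_error_io")
  )
  if (is.list(arr)) arr <- arr[[1]]
  if (length(dim(arr)) == 3 && dim(arr)[3] == 4) arr <- arr[, , 1:3]  # drop alpha
  if (length(dim(arr)) == 3) {
    return(to_grayscale(arr, px_size_um = px_size_um))
  }
  calibrated_image(as.matrix(arr), px_size_um)
}

#' Write a calibrated image to PNG or TIFF
#'
#' Intensities are clamped to \[0, 1\] and quantized: PNG is written as
#' 8-bit grayscale, TIFF at the requested bit depth (8 or 16).
#'
#' @param image A [calibrated_image()] or numeric matrix in \[0, 1\].
#' @param path Output path; format chosen from the extension.
#' @param bits TIFF bit depth, 8 or 16 (ignored for PNG).
#' @return `path`, invisibly.
#' @export
write_calibrated_image <- function(image, path, bits = 16) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  if (!bits %in% c(8, 16)) {
    abort("`bits` must be 8 or 16.", class = "airspace_error_validation")
  }
  px <- pmin(pmax(px, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = bits)
  } else {
    abort(sprintf("Unsupported image format '%s'.", ext),
          class = "airspace_error_io")
  }
  invisible(path)
}

#' Convert an RGB image to grayscale luminance
#'
#' Applies the Rec. 709 luminance weighting
#' `Y = 0.2126 R + 0.7152 G + 0.0722 B`. Grayscale input (a matrix or a
#' `calibrated_image`) is returned unchanged, so the conversion is
#' idempotent.
#'
#' @param image An H x W x 3 array in \[0, 1\], a numeric matrix, or a
#'   [calibrated_image()].
#' @param px_size_um Micrometers per pixel, required when `image` is a bare
#'   array or matrix.
#' @return A [calibrated_image()].
#' @export
to_grayscale <- function(image, px_size_um = NULL) {
  if (inherits(image, "calibrated_image")) return(image)
  if (is.null(px_size_um)) {
    abort("`px_size_um` is required for raw array input.",
          class = "airspace_error_validation")
  }
  if (is.matrix(image)) return(calibrated_image(image, px_size_um))
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) {
    abort(sprintf("RGB input must have 3 channels, got %s.",
                  paste(d, collapse = "x")),
          class = "airspace_error_validation")
  }
  y <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
  calibrated_image(y, px_size_um)
}
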