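#' Read an RGB image
#'
#' Reads a PNG, TIFF or JPEG file into the package's working representation:
#' a `height x width x 3` numeric array with channel values on the 0--255
#' scale (floating point; 8-bit quantization happens only when writing).
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @return A `height x width x 3` numeric array in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("reading TIFF requires the 'tiff' package.",
              class = "relcol_config_error")
      }
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        abort("reading JPEG requires the 'EBImage' package.",
              class = "relcol_config_error")
      }
      a <- EBImage::imageData(EBImage::readImage(path))
      # EBImage stores width x height x channel; transpose to height x width.
      aperm(a, c(2L, 1L, 3L))
    },
    abort(sprintf("unsupported image format '%s'.", ext),
          class = "relcol_config_error")
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an RGB image
#'
#' Writes a 0--255 RGB array to PNG (lossless, default), TIFF (lossless) or
#' JPEG.  Values are clamped and quantized to 8 bits at this point only.
#'
#' @param image `height x width x 3` numeric array in `[0, 255]`.
#' @param path Output path; format chosen from the extension.
#' @param quality JPEG quality in `[1, 100]`; ignored for lossless formats.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, quality = 90) {
  assert_rgb_image(image)
  x <- round(clamp(image, 0, 255)) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("writing TIFF requires the 'tiff' package.",
              class = "relcol_config_error")
      }
      tiff::writeTIFF(x, path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        abort("writing JPEG requires the 'EBImage' package.",
              class = "relcol_config_error")
      }
      EBImage::writeImage(
        EBImage::Image(aperm(x, c(2L, 1L, 3L)), colormode = "Color"),
        path, quality = quality)
    },
    abort(sprintf("unsupported image format '%s'.", ext),
          class = "relcol_config_error")
  )
  invisible(path)
}

#' Number of unique colors in an image
#'
#' @param image `height x width x 3` numeric array.
#' @return Integer count of distinct (R, G, B) triplets.
#' @export
n_unique_colors <- function(image) {
  px <- pixel_matrix(image)
  nrow(unique(px))
}
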