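# Grayscale image I/O (8-bit TIFF / PNG) on the package's matrix convention:
# numeric matrix [row = y, col = x], values 0-255.

#' Read an 8-bit grayscale image
#'
#' Reads a TIFF or PNG (chosen by file extension) into a 0-255 numeric
#' matrix; multi-channel images are rejected.
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @return Numeric matrix with values in 0-255.
#' @export
read_grayscale_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported image extension '.%s' (use TIFF or PNG)", ext),
         call. = FALSE))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1]
    else stop("multi-channel image: expected single-channel grayscale",
              call. = FALSE)
  }
  round(img * 255)
}

#' Write an 8-bit grayscale image
#'
#' @param image Numeric matrix with values in 0-255.
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_grayscale_image <- function(image, path) {
  stop_if_not_image(image)
  scaled <- round(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 8),
    png = png::writePNG(scaled, path),
    stop(sprintf("unsupported image extension '.%s' (use TIFF or PNG)", ext),
         call. = FALSE))
  invisible(path)
}

#' Write a label mask as 16-bit TIFF
#'
#' @param labeled A `labeled_mask` or integer label matrix.
#' @param path Output path ending in `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(labeled, path) {
  labels <- if (inherits(labeled, "labeled_mask")) labeled$labels else labeled
  if (max(labels) > 65535L) stop("more than 65535 labels", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}
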