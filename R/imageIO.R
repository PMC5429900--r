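#' @include AllClasses.R
NULL

#' Read an RGB section image from PNG or TIFF
#'
#' Accepts 8-bit-per-channel images; an alpha channel is dropped and a
#' grayscale plane is replicated to three channels. Returns the in-memory
#' representation used throughout the package: an H x W x 3 array of
#' integers in 0..255 (row = image row, origin top-left).
#'
#' @param path file path; format chosen by extension (.png, .tif, .tiff).
#' @return H x W x 3 numeric array of 8-bit values.
#' @seealso \code{\link{writeSectionImage}}
#' @export
readSectionImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)",
         call. = FALSE))
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] < 3L)
    stop("image must have 1, 3 or 4 channels", call. = FALSE)
  out <- round(x * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write an RGB image to PNG or TIFF
#'
#' @param image H x W x 3 array of 8-bit values (0-255).
#' @param path output path; format chosen by extension.
#' @return \code{path}, invisibly.
#' @export
writeSectionImage <- function(image, path) {
  .check_rgb_image(image)
  x <- image[, , 1:3, drop = FALSE] / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}
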