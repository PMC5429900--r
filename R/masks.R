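#' @include AllClasses.R
NULL

#' Label connected components of a binary mask
#'
#' Foreground components use 8-connectivity; together with 4-connected
#' background (as used for interior filling) this is the standard
#' complementary pair that avoids topological paradoxes when rings are
#' filled. Components are numbered in raster-scan (column-major) order of
#' their first pixel, so labels are deterministic.
#'
#' @param mask logical matrix.
#' @return Integer matrix of labels, 0 for background.
#' @export
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[4, 4] <- TRUE
#' max(labelComponents(m))  # diagonal pixels connect: 2 components
labelComponents <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!is.logical(mask)) mask <- mask != 0
  .label8_cpp(mask)
}

#' Fill the holes of a binary mask
#'
#' A hole is background not 4-connected to the image border. Filling a
#' closed ring yields its interior plus the ring itself.
#'
#' @param mask logical matrix.
#' @return Logical matrix with all holes filled.
#' @export
fillHoles <- function(mask) {
  stopifnot(is.matrix(mask))
  EBImage::fillHull(mask * 1L) > 0
}

# Morphological closing with a disc brush; radius 0 is the identity.
# The brush side is 2r+1 (odd), matching a Euclidean disc of radius r.
.close_disc <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::closing(mask * 1L, EBImage::makeBrush(2L * as.integer(radius) + 1L,
                                                 shape = "disc")) > 0
}

#' Write a binary mask as a single-channel PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask from a single-channel PNG
#'
#' @param path file path; any nonzero pixel is foreground.
#' @return Logical matrix.
#' @export
readMaskPNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x > 0
}

#' Run-length encode / decode a binary mask as plain text
#'
#' Column-major run-length encoding: a header line \code{nrow ncol} followed
#' by alternating run lengths starting with a background run (possibly 0).
#' A compact text representation for storing masks alongside CSV results.
#'
#' @param mask logical matrix.
#' @param text character as produced by \code{encodeMaskRLE}.
#' @return \code{encodeMaskRLE}: a single character string;
#'   \code{decodeMaskRLE}: the logical matrix.
#' @export
#' @examples
#' m <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)
#' identical(decodeMaskRLE(encodeMaskRLE(m)), m)
encodeMaskRLE <- function(mask) {
  stopifnot(is.matrix(mask))
  r <- rle(as.vector(mask != 0))
  if (length(r$lengths) && r$values[1]) {
    r$lengths <- c(0L, r$lengths)
  }
  paste(c(paste(nrow(mask), ncol(mask)), r$lengths), collapse = " ")
}

#' @rdname encodeMaskRLE
#' @export
decodeMaskRLE <- function(text) {
  v <- as.integer(strsplit(trimws(text), "\\s+")[[1]])
  nr <- v[1]; nc <- v[2]
  runs <- v[-(1:2)]
  vals <- rep(c(FALSE, TRUE), length.out = length(runs))
  matrix(rep(vals, runs), nr, nc)
}
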