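#' @include AllGenerics.R masks.R
NULL

#' Error signalled when no closed elastic lamina is found
#'
#' A condition of class \code{plaquemorph_no_vessel} carrying diagnostics:
#' the number of orcein-positive components examined and the largest
#' enclosed area seen.
#'
#' @param nComponents,largestEnclosed diagnostics.
#' @keywords internal
.no_vessel_error <- function(nComponents, largestEnclosed) {
  stop(structure(
    list(
      message = sprintf(
        "no vessel detected: %d orcein-positive component(s), largest enclosed area %d px",
        nComponents, as.integer(largestEnclosed)),
      call = NULL,
      nComponents = nComponents,
      largestEnclosed = largestEnclosed),
    class = c("plaquemorph_no_vessel", "error", "condition")))
}

# Perimeter of a binary mask via shape features; sums over components.
.perimeter <- function(mask) {
  if (!any(mask)) return(0)
  f <- EBImage::computeFeatures.shape(labelComponents(mask))
  sum(f[, "s.perimeter"])
}

#' Detect elastic laminae as thin closed rings in the orcein mask
#'
#' The purple (orcein) mask contains the elastic laminae but also cell
#' nuclei, fibrin and foam cells. Laminae are recognised purely
#' geometrically: each 8-connected component is morphologically closed
#' with a disc of \code{closingRadius} pixels (bridging broken laminae),
#' and is accepted as a lamina if the closed component encloses an
#' interior of at least \code{minEnclosedArea} pixels and its mean
#' thickness (ring area divided by the mean of inner and outer boundary
#' perimeter) is at most \code{maxThickness}. Compact blobs enclose
#' nothing and are rejected; thick filled structures fail the thickness
#' test. Accepted rings are ordered by enclosed area ascending (ties:
#' smaller component, then topmost, then leftmost centroid).
#'
#' @param elasticMask logical matrix, the ELASTIC_PURPLE class mask.
#' @param minEnclosedArea minimum filled-interior area (pixels).
#' @param closingRadius disc radius (pixels) for ring closure; 0 disables.
#' @param maxThickness maximum mean ring thickness (pixels).
#' @return A \code{\linkS4class{LaminaSet}}.
#' @section Errors: if no component passes the ring test, an error of
#'   condition class \code{plaquemorph_no_vessel} is raised carrying the
#'   component count and largest enclosed area as diagnostics.
#' @export
#' @examples
#' m <- matrix(FALSE, 101, 101)
#' d <- sqrt(outer((1:101 - 51)^2, (1:101 - 51)^2, "+"))
#' m[d >= 40 & d <= 44] <- TRUE
#' detectLaminae(m, minEnclosedArea = 100)
detectLaminae <- function(elasticMask, minEnclosedArea = 500,
                          closingRadius = 3, maxThickness = 15) {
  stopifnot(is.matrix(elasticMask))
  if (!is.logical(elasticMask)) elasticMask <- elasticMask != 0
  if (!any(elasticMask)) .no_vessel_error(0L, 0)

  lab <- labelComponents(elasticMask)
  ncomp <- max(lab)
  nr <- nrow(elasticMask); nc <- ncol(elasticMask)
  pix <- split(seq_along(lab)[lab > 0L], lab[lab > 0L])

  accepted <- list()
  largest_enclosed <- 0
  pad <- as.integer(closingRadius) + 1L
  for (k in seq_along(pix)) {
    idx <- pix[[k]]
    comp_area <- length(idx)
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    rr <- max(1L, min(rows) - pad):min(nr, max(rows) + pad)
    cc <- max(1L, min(cols) - pad):min(nc, max(cols) + pad)
    sub <- matrix(FALSE, length(rr), length(cc))
    sub[cbind(rows - rr[1L] + 1L, cols - cc[1L] + 1L)] <- TRUE
    closed <- .close_disc(sub, closingRadius)
    filled <- fillHoles(closed)
    enclosed <- sum(filled) - sum(closed)
    largest_enclosed <- max(largest_enclosed, enclosed)
    if (enclosed < minEnclosedArea) next
    interior <- filled & !closed
    thickness <- sum(closed) / (0.5 * (.perimeter(filled) + .perimeter(interior)))
    if (!is.finite(thickness) || thickness > maxThickness) next
    ring <- matrix(FALSE, nr, nc)
    ring[rr, cc] <- closed
    per_raw <- .perimeter(sub)
    accepted[[length(accepted) + 1L]] <- new("Lamina",
      ringMask = ring,
      componentArea = comp_area,
      enclosedArea = enclosed,
      meanThickness = thickness,
      elongation = per_raw^2 / comp_area,
      centroid = c(mean(rows), mean(cols)))
  }

  if (!length(accepted)) .no_vessel_error(ncomp, largest_enclosed)

  ea <- vapply(accepted, slot, numeric(1), "enclosedArea")
  ca <- vapply(accepted, slot, numeric(1), "componentArea")
  cr <- vapply(accepted, function(l) l@centroid[1], numeric(1))
  cl <- vapply(accepted, function(l) l@centroid[2], numeric(1))
  ord <- order(ea, ca, cr, cl)
  ls <- new("LaminaSet", laminae = accepted[ord])
  if (length(ord) > 1L) {
    fin <- fillHoles(innermost(ls)@ringMask)
    fout <- fillHoles(outermost(ls)@ringMask)
    if (any(fin & !fout))
      stop("laminae are not nested: innermost interior extends beyond the ",
           "outermost interior (multi-vessel images are unsupported)",
           call. = FALSE)
  }
  ls
}

#' @rdname accessors
#' @param allowSingle for \code{mediaMask} on a \code{LaminaSet} with one
#'   lamina: opt into the zero-width fallback (media = ring pixels only)
#'   instead of an error.
#' @param ... passed between methods.
#' @details On a \code{LaminaSet}, \code{mediaMask} computes the vessel
#'   media: the filled interior of the outermost lamina (ring included)
#'   minus the strict interior of the innermost lamina. The innermost ring
#'   pixels belong to the media (the inner lamina outlines, but is not part
#'   of, the internal area). \code{internalMask} computes the internal
#'   vessel area (plaque + lumen): the strict filled interior of the
#'   innermost lamina, ring pixels excluded; it is disjoint from the media
#'   by construction.
setMethod("mediaMask", "LaminaSet", function(x, allowSingle = FALSE, ...) {
  if (length(x@laminae) < 2L && !allowSingle)
    stop("cannot delimit media: only one lamina detected ",
         "(set allowSingle = TRUE for a zero-width media fallback)",
         call. = FALSE)
  inner <- innermost(x)@ringMask
  outer <- outermost(x)@ringMask
  strict_inner <- fillHoles(inner) & !inner
  fillHoles(outer) & !strict_inner
})

#' @rdname accessors
setMethod("internalMask", "LaminaSet", function(x, ...) {
  inner <- innermost(x)@ringMask
  fillHoles(inner) & !inner
})
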