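#' @include laminae.R colorModel.R
NULL

#' Segmentation parameters
#'
#' Bundles the tunable parameters of \code{\link{segmentSection}}.
#' \code{minRbcPixels} is resolution-aware: one murine erythrocyte
#' (~5 um across) spans about 10 pixels at 0.5 um/px, and the count scales
#' with the inverse square of the calibration; use
#' \code{\link{defaultMinRbcPixels}} to rescale.
#'
#' @param minEnclosedArea minimum lamina interior (pixels, default 500).
#' @param closingRadius disc radius for ring closure (pixels, default 3).
#' @param maxThickness maximum mean lamina thickness (pixels, default 15).
#' @param minRbcPixels erythrocyte pixels required to call a white
#'   component lumen (default 10, for 0.5 um/px).
#' @return A named list of parameters.
#' @export
segmentationParams <- function(minEnclosedArea = 500, closingRadius = 3,
                               maxThickness = 15, minRbcPixels = 10) {
  stopifnot(minEnclosedArea > 0, closingRadius >= 0, maxThickness > 0,
            minRbcPixels >= 1)
  list(minEnclosedArea = minEnclosedArea, closingRadius = closingRadius,
       maxThickness = maxThickness, minRbcPixels = minRbcPixels)
}

#' Resolution-aware erythrocyte pixel threshold
#'
#' @param micronsPerPixel spatial calibration (um/px).
#' @param refPixels,refCalibration the reference: 10 px at 0.5 um/px.
#' @return Pixel count scaled by (refCalibration / micronsPerPixel)^2.
#' @export
#' @examples
#' defaultMinRbcPixels(0.25)  # finer sampling: 40 px
defaultMinRbcPixels <- function(micronsPerPixel, refPixels = 10,
                                refCalibration = 0.5) {
  stopifnot(micronsPerPixel > 0, is.finite(micronsPerPixel))
  refPixels * (refCalibration / micronsPerPixel)^2
}

#' Split the internal area's white regions into lumen and lipid
#'
#' Candidate regions are the 8-connected components of
#' (white OR erythrocyte) pixels inside the internal area. A component
#' that contains white pixels and at least \code{minRbcPixels} erythrocyte
#' pixels is lumen (its erythrocyte pixels included); white components
#' without that many erythrocytes are lipid. Components made of
#' erythrocyte pixels only (red blood cells entrapped in the plaque
#' matrix) are neither: the lumen rule keys on white-component
#' membership, not on erythrocytes alone.
#'
#' @param internal logical matrix, the internal vessel area.
#' @param whiteMask,erythrocyteMask logical matrices from
#'   \code{\link{classMask}}.
#' @param minRbcPixels erythrocyte pixel threshold (>= 1).
#' @return A list with logical matrices \code{lumen} and \code{lipid}
#'   (disjoint, both subsets of \code{internal}).
#' @section Warnings: a section may graze the vessel so that no
#'   erythrocytes are present; an empty lumen is returned with a warning.
#' @export
splitLumenLipid <- function(internal, whiteMask, erythrocyteMask,
                            minRbcPixels = 10) {
  stopifnot(is.matrix(internal), .same_dim(internal, whiteMask),
            .same_dim(internal, erythrocyteMask), minRbcPixels >= 1)
  cand <- (whiteMask | erythrocyteMask) & internal
  lumen <- matrix(FALSE, nrow(internal), ncol(internal))
  lipid <- lumen
  if (any(cand)) {
    lab <- labelComponents(cand)
    n <- max(lab)
    n_white <- tabulate(lab[whiteMask & cand], nbins = n)
    n_rbc <- tabulate(lab[erythrocyteMask & cand & !whiteMask], nbins = n)
    is_lumen <- n_white > 0L & n_rbc >= minRbcPixels
    is_lipid <- n_white > 0L & !is_lumen
    # index shifted by one so background (label 0) maps to FALSE
    lumen <- matrix(c(FALSE, is_lumen)[lab + 1L], nrow(lab), ncol(lab))
    lipid <- matrix(c(FALSE, is_lipid)[lab + 1L], nrow(lab), ncol(lab))
  }
  if (!any(lumen))
    warning("no lumen found (no white region with >= ", minRbcPixels,
            " erythrocyte pixels); the section may graze the vessel",
            call. = FALSE)
  list(lumen = lumen, lipid = lipid)
}

#' Plaque area by subtraction
#'
#' The plaque occupies the internal vessel area not taken by the lumen:
#' internal pixel count minus lumen pixel count.
#'
#' @param internal,lumen logical matrices with \code{lumen} a subset of
#'   \code{internal}.
#' @return Pixel count (non-negative).
#' @export
plaquePixels <- function(internal, lumen) {
  stopifnot(is.matrix(internal), .same_dim(internal, lumen))
  if (any(lumen & !internal))
    stop("invariant violation: lumen extends outside the internal area",
         call. = FALSE)
  sum(internal) - sum(lumen)
}

#' Collagen inside the plaque
#'
#' Blue (methyl blue) pixels restricted to the plaque:
#' \code{blueMask & internal & !lumen}.
#'
#' @param blueMask,internal,lumen logical matrices of equal dimensions.
#' @return Logical matrix.
#' @export
collagenInPlaque <- function(blueMask, internal, lumen) {
  stopifnot(is.matrix(blueMask), .same_dim(blueMask, internal),
            .same_dim(blueMask, lumen))
  blueMask & internal & !lumen
}

#' Segment one OMSB-stained artery cross-section
#'
#' Runs the full mask-construction algorithm: (1) classify pixels by color
#' (\code{\link{classifyPixels}}); (2) detect elastic laminae as thin
#' closed rings in the purple mask (\code{\link{detectLaminae}});
#' (3) media = area between the innermost and outermost lamina, internal
#' = strict interior of the innermost lamina; (4) split white regions of
#' the internal area into lumen (with erythrocytes) and lipid (without);
#' (5) plaque = internal minus lumen, and collagen is masked inside the
#' plaque by blue thresholding.
#'
#' @param image H x W x 3 array of 8-bit RGB values.
#' @param config a \code{\linkS4class{ColorConfig}}.
#' @param params a list from \code{\link{segmentationParams}}.
#' @return A \code{\linkS4class{SegmentationResult}}.
#' @section Errors: propagates the \code{plaquemorph_no_vessel} condition
#'   of \code{\link{detectLaminae}} (e.g. on a blank image).
#' @export
#' @examples
#' tr <- generateSection(sectionSpec(seed = 1))
#' seg <- segmentSection(tr$image)
#' seg
segmentSection <- function(image, config = defaultColorConfig(),
                           params = segmentationParams()) {
  cm <- classifyPixels(image, config)
  purple <- classMask(cm, "ELASTIC_PURPLE")
  ls <- detectLaminae(purple,
                      minEnclosedArea = params$minEnclosedArea,
                      closingRadius = params$closingRadius,
                      maxThickness = params$maxThickness)
  single <- length(ls@laminae) < 2L
  media <- mediaMask(ls, allowSingle = single)
  internal <- internalMask(ls)
  ll <- splitLumenLipid(internal,
                        whiteMask = classMask(cm, "WHITE"),
                        erythrocyteMask = classMask(cm, "ERYTHROCYTE_YELLOW"),
                        minRbcPixels = params$minRbcPixels)
  cg <- collagenInPlaque(classMask(cm, "COLLAGEN_BLUE"), internal, ll$lumen)
  new("SegmentationResult",
      media = media, internal = internal, lumen = ll$lumen,
      lipid = ll$lipid, collagenInPlaque = cg, laminae = ls, classMap = cm)
}

#' Summarize a segmentation as a JSON string
#'
#' Pixel counts per compartment plus lamina descriptors; suitable for
#' writing next to the mask images.
#'
#' @param seg a \code{\linkS4class{SegmentationResult}}.
#' @return A JSON character string.
#' @export
segmentationSummary <- function(seg) {
  stopifnot(is(seg, "SegmentationResult"))
  lam <- lapply(seg@laminae@laminae, function(l) list(
    componentArea = l@componentArea, enclosedArea = l@enclosedArea,
    meanThickness = round(l@meanThickness, 2),
    centroid = round(l@centroid, 1)))
  jsonlite::toJSON(list(
    pixels = list(
      media = sum(seg@media), internal = sum(seg@internal),
      lumen = sum(seg@lumen), plaque = plaquePixelCount(seg),
      lipid = sum(seg@lipid), collagenInPlaque = sum(seg@collagenInPlaque)),
    laminae = lam), auto_unbox = TRUE, digits = NA)
}
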