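#' @include AllClasses.R
NULL

#' Accessors for segmentation and lamina objects
#'
#' \code{innermost}/\code{outermost} return the lamina with the smallest /
#' largest enclosed area; \code{laminae} the ordered list. On a
#' \code{SegmentationResult}, \code{mediaMask}, \code{internalMask},
#' \code{lumenMask}, \code{lipidMask} and \code{collagenMask} return the
#' stored compartment masks and \code{plaquePixelCount} the derived plaque
#' pixel count (internal minus lumen).
#'
#' @param x a \code{\linkS4class{LaminaSet}} or
#'   \code{\linkS4class{SegmentationResult}}.
#' @return A \code{\linkS4class{Lamina}}, a list, a logical matrix, or a
#'   count, respectively.
#' @name accessors
#' @examples
#' tr <- generateSection(sectionSpec(seed = 7))
#' seg <- segmentSection(tr$image)
#' plaquePixelCount(seg)
#' innermost(laminaSet(seg))@enclosedArea
NULL

#' @rdname accessors
#' @export
setGeneric("laminae", function(x) standardGeneric("laminae"))
#' @rdname accessors
#' @export
setGeneric("innermost", function(x) standardGeneric("innermost"))
#' @rdname accessors
#' @export
setGeneric("outermost", function(x) standardGeneric("outermost"))
#' @rdname accessors
#' @export
setGeneric("laminaSet", function(x) standardGeneric("laminaSet"))
#' @rdname accessors
#' @export
setGeneric("mediaMask", function(x, ...) standardGeneric("mediaMask"))
#' @rdname accessors
#' @export
setGeneric("internalMask", function(x, ...) standardGeneric("internalMask"))
#' @rdname accessors
#' @export
setGeneric("lumenMask", function(x) standardGeneric("lumenMask"))
#' @rdname accessors
#' @export
setGeneric("lipidMask", function(x) standardGeneric("lipidMask"))
#' @rdname accessors
#' @export
setGeneric("collagenMask", function(x) standardGeneric("collagenMask"))
#' @rdname accessors
#' @export
setGeneric("plaquePixelCount", function(x) standardGeneric("plaquePixelCount"))

#' @rdname accessors
setMethod("laminae", "LaminaSet", function(x) x@laminae)
#' @rdname accessors
setMethod("innermost", "LaminaSet", function(x) x@laminae[[1L]])
#' @rdname accessors
setMethod("outermost", "LaminaSet", function(x) x@laminae[[length(x@laminae)]])
#' @rdname accessors
setMethod("laminaSet", "SegmentationResult", function(x) x@laminae)
#' @rdname accessors
setMethod("mediaMask", "SegmentationResult", function(x) x@media)
#' @rdname accessors
setMethod("internalMask", "SegmentationResult", function(x) x@internal)
#' @rdname accessors
setMethod("lumenMask", "SegmentationResult", function(x) x@lumen)
#' @rdname accessors
setMethod("lipidMask", "SegmentationResult", function(x) x@lipid)
#' @rdname accessors
setMethod("collagenMask", "SegmentationResult", function(x) x@collagenInPlaque)
#' @rdname accessors
setMethod("plaquePixelCount", "SegmentationResult",
          function(x) sum(x@internal) - sum(x@lumen))

setMethod("show", "ColorConfig", function(object) {
  cat("ColorConfig (HSV thresholds)\n")
  cat(sprintf("  WHITE: value >= %.2f and saturation <= %.2f\n",
              object@whiteMinValue, object@whiteMaxSaturation))
  hr <- object@hueRanges
  for (cl in rownames(hr))
    cat(sprintf("  %s: hue %g-%g deg\n", cl, hr[cl, 1], hr[cl, 2]))
  cat(sprintf("  chroma gates: saturation >= %.2f, value >= %.2f (else OTHER)\n",
              object@minSaturation, object@minValue))
})

setMethod("show", "ClassMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("ClassMap %d x %d pixels\n", d[1], d[2]))
  cnt <- classCounts(object)
  for (cl in names(cnt))
    cat(sprintf("  %-18s %8d px (%.1f%%)\n", cl, cnt[[cl]],
                100 * cnt[[cl]] / prod(d)))
})

setMethod("show", "Lamina", function(object) {
  cat(sprintf(
    "Lamina: component %d px, enclosed %d px, mean thickness %.1f px, centroid (%.0f, %.0f)\n",
    object@componentArea, object@enclosedArea, object@meanThickness,
    object@centroid[1], object@centroid[2]))
})

setMethod("show", "LaminaSet", function(object) {
  cat(sprintf("LaminaSet of %d lamina(e), innermost to outermost:\n",
              length(object@laminae)))
  for (l in object@laminae) show(l)
})

setMethod("show", "SegmentationResult", function(object) {
  d <- dim(object@media)
  cat(sprintf("SegmentationResult %d x %d pixels\n", d[1], d[2]))
  cat(sprintf("  media    %8d px\n", sum(object@media)))
  cat(sprintf("  internal %8d px (lumen %d + plaque %d)\n",
              sum(object@internal), sum(object@lumen), plaquePixelCount(object)))
  cat(sprintf("  lipid    %8d px, collagen in plaque %d px\n",
              sum(object@lipid), sum(object@collagenInPlaque)))
  cat(sprintf("  laminae: %d ring(s)\n", length(object@laminae@laminae)))
})

setMethod("show", "MorphometryRecord", function(object) {
  cat(sprintf("MorphometryRecord '%s' (%s)\n", object@sectionId,
              object@segmentLabel))
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
  cat(sprintf("  media  %12.1f um2 (%s%%)\n", object@mediaArea,
              fmt(object@relativeMedia)))
  cat(sprintf("  lumen  %12.1f um2 (%s%%)\n", object@lumenArea,
              fmt(object@relativeLumen)))
  cat(sprintf("  plaque %12.1f um2 (%s%%)\n", object@plaqueArea,
              fmt(object@relativePlaque)))
  cat(sprintf("  collagen %10s um2 (%s%% of plaque)\n",
              fmt(object@collagenArea), fmt(object@relativeCollagen)))
  cat(sprintf("  lipid  %12s um2 (%s%% of plaque)\n",
              fmt(object@lipidArea), fmt(object@relativeLipid)))
  cat(sprintf("  total vessel %8.1f um2\n", object@totalVesselArea))
})

setMethod("show", "SectionSpec", function(object) {
  cat(sprintf("SectionSpec %dx%d px, %d lamina(e), lumen r=%.0f, seed %d\n",
              object@size, object@size, length(object@laminaRadii),
              object@lumenRadius, object@seed))
})

setMethod("show", "SyntheticGroundTruth", function(object) {
  cat("SyntheticGroundTruth areas (px):\n")
  print(round(object@areasPx))
})
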