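#' @include plaquemorph-package.R
NULL

.is_binary_mask <- function(x) {
  is.matrix(x) && is.logical(x) && !anyNA(x)
}

.same_dim <- function(a, b) identical(dim(a), dim(b))

#' ColorConfig: HSV thresholds for stain classification
#'
#' Holds the per-class hue sectors (degrees), the achromatic WHITE rule
#' (brightness floor and saturation ceiling), the chroma gates below which a
#' pixel is labelled \code{OTHER}, and one prototype RGB color per class
#' (used by the synthetic renderer and for sanity checks).
#'
#' Classification priority: WHITE first, then the chromatic classes in the
#' order of \code{hueRanges} rows, then \code{OTHER}. Hue ranges may wrap
#' modulo 360 (low > high means the sector crosses 0).
#'
#' @slot whiteMinValue numeric, HSV value floor for WHITE (default 0.85).
#' @slot whiteMaxSaturation numeric, saturation ceiling for WHITE (0.15).
#' @slot hueRanges 4x2 numeric matrix (columns \code{low}, \code{high},
#'   degrees) with rows \code{ERYTHROCYTE_YELLOW}, \code{COLLAGEN_BLUE},
#'   \code{ELASTIC_PURPLE}, \code{RED_PINK}.
#' @slot minSaturation,minValue chroma gates for the chromatic classes.
#' @slot prototypes 5x3 integer matrix of prototype RGB colors (0-255),
#'   rows named by class (all classes except OTHER).
#' @seealso \code{\link{defaultColorConfig}}, \code{\link{classifyPixels}}
#' @exportClass ColorConfig
setClass("ColorConfig",
  representation(
    whiteMinValue = "numeric",
    whiteMaxSaturation = "numeric",
    hueRanges = "matrix",
    minSaturation = "numeric",
    minValue = "numeric",
    prototypes = "matrix"
  )
)

setValidity("ColorConfig", function(object) {
  msg <- character()
  u <- c(object@whiteMinValue, object@whiteMaxSaturation,
         object@minSaturation, object@minValue)
  if (length(u) != 4L || anyNA(u) || any(u < 0) || any(u > 1))
    msg <- c(msg, "white/chroma thresholds must be single values in [0, 1]")
  hr <- object@hueRanges
  chromatic <- setdiff(STAIN_CLASSES, c("WHITE", "OTHER"))
  if (!is.numeric(hr) || ncol(hr) != 2L ||
      !setequal(rownames(hr), chromatic))
    msg <- c(msg, "hueRanges must be a numeric matrix with one (low, high) row per chromatic class")
  else if (anyNA(hr) || any(hr < 0) || any(hr >= 360))
    msg <- c(msg, "hue bounds must lie in [0, 360)")
  pr <- object@prototypes
  if (!is.numeric(pr) || ncol(pr) != 3L ||
      !all(setdiff(STAIN_CLASSES, "OTHER") %in% rownames(pr)))
    msg <- c(msg, "prototypes must give an RGB row for every class except OTHER")
  else if (anyNA(pr) || any(pr < 0) || any(pr > 255) || any(pr != round(pr)))
    msg <- c(msg, "prototype colors must be 8-bit RGB values")
  if (length(msg)) msg else TRUE
})

#' ClassMap: per-pixel stain-class labels
#'
#' Result of \code{\link{classifyPixels}}: an integer matrix of codes into
#' \code{\link{stainClasses}()}, same dimensions as the source image. Every
#' pixel carries exactly one label (the classes partition the image).
#'
#' @slot labels integer matrix of codes in \code{1:6}.
#' @slot classes the label names the codes index (fixed to
#'   \code{stainClasses()}).
#' @seealso \code{\link{classMask}}, \code{\link{classCounts}}
#' @exportClass ClassMap
setClass("ClassMap",
  representation(labels = "matrix", classes = "character")
)

setValidity("ClassMap", function(object) {
  msg <- character()
  if (!is.integer(object@labels) || anyNA(object@labels))
    msg <- c(msg, "labels must be an integer matrix without NA")
  if (!identical(object@classes, STAIN_CLASSES))
    msg <- c(msg, "classes must be the canonical stain-class vector")
  else if (length(object@labels) &&
           (min(object@labels) < 1L || max(object@labels) > length(object@classes)))
    msg <- c(msg, "label codes out of range")
  if (length(msg)) msg else TRUE
})

#' Lamina: one elastic lamina accepted as a closed ring
#'
#' A connected component of the purple (orcein) mask that, after
#' morphological closing, encloses an interior. Thin closed rings are what
#' distinguishes laminae from the nuclei/fibrin/foam-cell blobs that share
#' the orcein color.
#'
#' @slot ringMask logical matrix: the component after closing.
#' @slot componentArea pixels of the raw (pre-closing) component.
#' @slot enclosedArea pixels of the strict filled interior.
#' @slot meanThickness pixels: ring area / mean of inner and outer boundary
#'   perimeter.
#' @slot elongation perimeter^2 / area of the raw component (descriptor).
#' @slot centroid numeric (row, col) of the raw component.
#' @exportClass Lamina
setClass("Lamina",
  representation(
    ringMask = "matrix",
    componentArea = "numeric",
    enclosedArea = "numeric",
    meanThickness = "numeric",
    elongation = "numeric",
    centroid = "numeric"
  )
)

setValidity("Lamina", function(object) {
  msg <- character()
  if (!.is_binary_mask(object@ringMask))
    msg <- c(msg, "ringMask must be a logical matrix")
  if (length(object@enclosedArea) != 1L || is.na(object@enclosedArea) ||
      object@enclosedArea <= 0)
    msg <- c(msg, "a ring lamina must enclose a positive interior")
  if (length(object@centroid) != 2L)
    msg <- c(msg, "centroid must be (row, col)")
  if (length(msg)) msg else TRUE
})

#' LaminaSet: the laminae of one section, ordered inside-out
#'
#' Laminae sorted by enclosed (filled) area ascending; ties broken by
#' smaller component pixel count, then by topmost, then leftmost centroid.
#' The first element is the innermost lamina (it outlines the internal
#' vessel area) and the last the outermost; the innermost interior must be
#' nested inside the outermost interior.
#'
#' @slot laminae list of \code{\linkS4class{Lamina}}.
#' @seealso \code{\link{detectLaminae}}, \code{\link{innermost}},
#'   \code{\link{outermost}}
#' @exportClass LaminaSet
setClass("LaminaSet", representation(laminae = "list"))

setValidity("LaminaSet", function(object) {
  msg <- character()
  if (!length(object@laminae))
    msg <- c(msg, "LaminaSet must contain at least one lamina")
  if (!all(vapply(object@laminae, is, logical(1), "Lamina")))
    msg <- c(msg, "laminae must all be Lamina objects")
  else {
    ea <- vapply(object@laminae, slot, numeric(1), "enclosedArea")
    if (is.unsorted(ea)) msg <- c(msg, "laminae must be ordered by enclosed area")
  }
  if (length(msg)) msg else TRUE
})

#' SegmentationResult: the named compartment masks of one section
#'
#' Binary masks produced by the segmentation rules: \code{media} (between
#' the innermost and outermost elastic lamina, the innermost ring pixels
#' included), \code{internal} (strict interior of the innermost lamina:
#' plaque + lumen), \code{lumen} (white region containing erythrocytes),
#' \code{lipid} (white regions in plaque without erythrocytes) and
#' \code{collagenInPlaque}. The plaque area is derived by subtraction
#' (internal minus lumen pixels), not stored as a mask.
#'
#' @slot media,internal,lumen,lipid,collagenInPlaque logical matrices.
#' @slot laminae the \code{\linkS4class{LaminaSet}} used.
#' @slot classMap the \code{\linkS4class{ClassMap}} of the section.
#' @seealso \code{\link{segmentSection}}, \code{\link{plaquePixels}}
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(
    media = "matrix",
    internal = "matrix",
    lumen = "matrix",
    lipid = "matrix",
    collagenInPlaque = "matrix",
    laminae = "LaminaSet",
    classMap = "ClassMap"
  )
)

setValidity("SegmentationResult", function(object) {
  m <- object@media; i <- object@internal; l <- object@lumen
  p <- object@lipid; cg <- object@collagenInPlaque
  masks <- list(media = m, internal = i, lumen = l, lipid = p,
                collagenInPlaque = cg)
  if (!all(vapply(masks, .is_binary_mask, logical(1))))
    return("all compartment masks must be logical matrices")
  if (!all(vapply(masks[-1], .same_dim, logical(1), b = m)))
    return("compartment masks must share dimensions")
  msg <- character()
  if (any(m & i)) msg <- c(msg, "media and internal must be disjoint")
  if (any(l & !i)) msg <- c(msg, "lumen must be contained in internal")
  if (any(p & !i)) msg <- c(msg, "lipid must be contained in internal")
  if (any(l & p)) msg <- c(msg, "lumen and lipid must be disjoint")
  if (any(cg & !i) || any(cg & l))
    msg <- c(msg, "collagenInPlaque must lie in internal minus lumen")
  if (length(msg)) msg else TRUE
})

#' MorphometryRecord: calibrated areas and relative parameters of a section
#'
#' Absolute compartment areas in square microns and the derived relative
#' parameters: total vessel area = media + lumen + plaque; relative lumen
#' and plaque (and media) are percentages of total vessel area; relative
#' collagen and lipid are percentages of plaque area. Ratios with a zero
#' denominator are \code{NA} (undefined), never silently zero.
#'
#' @slot sectionId character identifier.
#' @slot segmentLabel one of \code{"proximal"}, \code{"distal"},
#'   \code{"unspecified"}.
#' @slot mediaArea,lumenArea,plaqueArea,collagenArea,lipidArea,totalVesselArea
#'   numeric, square microns (collagen/lipid may be NA when unmeasured, as
#'   in manual tracing).
#' @slot relativeMedia,relativeLumen,relativePlaque,relativeCollagen,relativeLipid
#'   numeric percentages in [0, 100] or NA.
#' @seealso \code{\link{computeMorphometry}}, \code{\link{morphometryFromAreas}}
#' @exportClass MorphometryRecord
setClass("MorphometryRecord",
  representation(
    sectionId = "character",
    segmentLabel = "character",
    mediaArea = "numeric",
    lumenArea = "numeric",
    plaqueArea = "numeric",
    collagenArea = "numeric",
    lipidArea = "numeric",
    totalVesselArea = "numeric",
    relativeMedia = "numeric",
    relativeLumen = "numeric",
    relativePlaque = "numeric",
    relativeCollagen = "numeric",
    relativeLipid = "numeric"
  )
)

setValidity("MorphometryRecord", function(object) {
  msg <- character()
  if (!object@segmentLabel %in% c("proximal", "distal", "unspecified"))
    msg <- c(msg, "segmentLabel must be proximal, distal or unspecified")
  abs_ <- c(object@mediaArea, object@lumenArea, object@plaqueArea)
  if (anyNA(abs_) || any(abs_ < 0))
    msg <- c(msg, "media, lumen and plaque areas must be non-negative")
  tva <- object@totalVesselArea
  if (is.na(tva) || abs(tva - sum(abs_)) > 1e-6 * max(1, tva))
    msg <- c(msg, "totalVesselArea must equal media + lumen + plaque")
  rel <- c(object@relativeMedia, object@relativeLumen, object@relativePlaque,
           object@relativeCollagen, object@relativeLipid)
  rel <- rel[!is.na(rel)]
  if (any(rel < 0 | rel > 100))
    msg <- c(msg, "relative parameters must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' SectionSpec: geometry of one synthetic OMSB-like section
#'
#' Describes an idealised artery cross-section: concentric elastic laminae
#' (annuli, optionally broken by an angular gap), an eccentric circular
#' lumen inside the innermost lamina, collagen blobs and lipid vacuoles in
#' the plaque, erythrocyte disks in the lumen (optionally a few entrapped
#' in plaque), and per-channel Gaussian color noise.
#'
#' @slot size image side length in pixels (square image).
#' @slot center numeric (row, col) of the vessel center.
#' @slot laminaRadii list of c(inner, outer) pixel radii, strictly nested.
#' @slot laminaBreaks list (same length) of NULL or c(start, extent)
#'   degrees: an arc of the ring left unpainted (a broken lamina).
#' @slot lumenRadius,lumenOffset lumen disk radius and (row, col) offset of
#'   its center from the vessel center.
#' @slot collagenBlobs,collagenRadius count and mean radius of blue blobs.
#' @slot lipidVacuoles,lipidRadius count and mean radius of white vacuoles.
#' @slot erythrocytes,erythrocyteRadius count and radius of yellow disks in
#'   the lumen.
#' @slot entrappedErythrocytes count of erythrocyte disks scattered in the
#'   plaque matrix (intraplaque hemorrhage); these are plaque, not lumen.
#' @slot noiseSd per-channel Gaussian noise, 8-bit intensity levels.
#' @slot seed integer RNG seed; rendering is bit-reproducible per seed.
#' @seealso \code{\link{sectionSpec}}, \code{\link{generateSection}}
#' @exportClass SectionSpec
setClass("SectionSpec",
  representation(
    size = "integer",
    center = "numeric",
    laminaRadii = "list",
    laminaBreaks = "list",
    lumenRadius = "numeric",
    lumenOffset = "numeric",
    collagenBlobs = "integer",
    collagenRadius = "numeric",
    lipidVacuoles = "integer",
    lipidRadius = "numeric",
    erythrocytes = "integer",
    erythrocyteRadius = "numeric",
    entrappedErythrocytes = "integer",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SectionSpec", function(object) {
  msg <- character()
  if (object@size < 16L) msg <- c(msg, "image size too small")
  rr <- object@laminaRadii
  if (!length(rr)) msg <- c(msg, "at least one lamina is required")
  else {
    ok <- vapply(rr, function(r) length(r) == 2L && r[1] > 0 && r[1] < r[2],
                 logical(1))
    if (!all(ok)) msg <- c(msg, "each lamina needs radii 0 < inner < outer")
    else {
      flat <- unlist(rr)
      if (length(rr) > 1L) {
        outer_prev <- vapply(rr[-length(rr)], `[`, numeric(1), 2L)
        inner_next <- vapply(rr[-1L], `[`, numeric(1), 1L)
        if (any(outer_prev >= inner_next))
          msg <- c(msg, "lamina annuli must be strictly nested and non-overlapping")
      }
      if (max(flat) + 2 > min(object@center, object@size - object@center + 1))
        msg <- c(msg, "outermost lamina does not fit in the image")
      if (object@lumenRadius + sqrt(sum(object@lumenOffset^2)) >= rr[[1]][1])
        msg <- c(msg, "lumen must lie strictly inside the innermost lamina")
    }
  }
  if (length(object@laminaBreaks) != length(rr))
    msg <- c(msg, "laminaBreaks must have one entry (possibly NULL) per lamina")
  else {
    ext <- vapply(object@laminaBreaks,
                  function(b) if (is.null(b)) 0 else b[2], numeric(1))
    if (any(ext < 0 | ext >= 360)) msg <- c(msg, "break arcs must lie in [0, 360)")
  }
  cnt <- c(object@collagenBlobs, object@lipidVacuoles, object@erythrocytes,
           object@entrappedErythrocytes)
  if (any(cnt < 0L)) msg <- c(msg, "counts must be non-negative")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SyntheticGroundTruth: exact masks and areas of a generated section
#'
#' The per-compartment truth recorded by \code{\link{generateSection}}
#' before noise is added. The masks satisfy the same algebra as a
#' \code{\linkS4class{SegmentationResult}}; areas are mask pixel counts.
#'
#' @slot media,internal,lumen,lipid,collagen logical matrices.
#' @slot areasPx named numeric: media, internal, lumen, plaque, lipid,
#'   collagen (pixels; plaque = internal - lumen).
#' @slot spec the \code{\linkS4class{SectionSpec}} used.
#' @exportClass SyntheticGroundTruth
setClass("SyntheticGroundTruth",
  representation(
    media = "matrix",
    internal = "matrix",
    lumen = "matrix",
    lipid = "matrix",
    collagen = "matrix",
    areasPx = "numeric",
    spec = "SectionSpec"
  )
)

setValidity("SyntheticGroundTruth", function(object) {
  msg <- character()
  need <- c("media", "internal", "lumen", "plaque", "lipid", "collagen")
  if (!all(need %in% names(object@areasPx)))
    msg <- c(msg, "areasPx must name media, internal, lumen, plaque, lipid, collagen")
  else {
    a <- object@areasPx
    if (a[["media"]] != sum(object@media) || a[["lumen"]] != sum(object@lumen) ||
        a[["internal"]] != sum(object@internal) ||
        a[["lipid"]] != sum(object@lipid) || a[["collagen"]] != sum(object@collagen))
      msg <- c(msg, "areas must equal mask pixel counts")
    if (a[["plaque"]] != a[["internal"]] - a[["lumen"]])
      msg <- c(msg, "plaque area must be internal minus lumen")
  }
  if (any(object@lumen & !object@internal) || any(object@media & object@internal))
    msg <- c(msg, "ground-truth masks violate the segmentation algebra")
  if (length(msg)) msg else TRUE
})
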