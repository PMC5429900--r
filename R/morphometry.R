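#' @include segmentation.R
NULL

.check_calibration <- function(micronsPerPixel) {
  if (!is.numeric(micronsPerPixel) || length(micronsPerPixel) != 1L ||
      !is.finite(micronsPerPixel) || micronsPerPixel <= 0)
    stop("micronsPerPixel must be a single positive finite number",
         call. = FALSE)
  invisible(TRUE)
}

.make_record <- function(mediaArea, lumenArea, plaqueArea,
                         collagenArea, lipidArea,
                         sectionId, segmentLabel, warnCollagen = TRUE) {
  tva <- mediaArea + lumenArea + plaqueArea
  if (tva <= 0) stop("zero total vessel area", call. = FALSE)
  rel_of <- function(x, denom) {
    if (is.na(x) || denom == 0) NA_real_ else 100 * x / denom
  }
  if (plaqueArea == 0 && warnCollagen &&
      ((!is.na(collagenArea) && collagenArea > 0) ||
       (!is.na(lipidArea) && lipidArea > 0)))
    warning("plaque area is zero: relative collagen/lipid are undefined",
            call. = FALSE)
  new("MorphometryRecord",
      sectionId = as.character(sectionId),
      segmentLabel = segmentLabel,
      mediaArea = mediaArea, lumenArea = lumenArea, plaqueArea = plaqueArea,
      collagenArea = collagenArea, lipidArea = lipidArea,
      totalVesselArea = tva,
      relativeMedia = rel_of(mediaArea, tva),
      relativeLumen = rel_of(lumenArea, tva),
      relativePlaque = rel_of(plaqueArea, tva),
      relativeCollagen = rel_of(collagenArea, plaqueArea),
      relativeLipid = rel_of(lipidArea, plaqueArea))
}

#' Calibrated morphometry of a segmented section
#'
#' Converts pixel counts to absolute areas (pixel count times the square
#' of the calibration, in square microns) and derives the standard
#' relative parameters: total vessel area = media + lumen + plaque;
#' relative lumen = lumen / total x 100%; relative plaque = plaque /
#' total x 100%; relative collagen = collagen / plaque x 100%; relative
#' lipid = lipid / plaque x 100%. Relative media is computed as well.
#' Arithmetic is kept at full floating precision; any rounding is
#' presentation-only. Ratios over a zero plaque are \code{NA}
#' (undefined), never zero.
#'
#' @param seg a \code{\linkS4class{SegmentationResult}}.
#' @param micronsPerPixel spatial calibration (um/px, > 0).
#' @param sectionId identifier stored in the record.
#' @param segmentLabel \code{"proximal"}, \code{"distal"} or
#'   \code{"unspecified"}.
#' @return A \code{\linkS4class{MorphometryRecord}}.
#' @export
#' @examples
#' tr <- generateSection(sectionSpec(seed = 1))
#' computeMorphometry(segmentSection(tr$image), micronsPerPixel = 0.5, "s1")
computeMorphometry <- function(seg, micronsPerPixel, sectionId = "section",
                               segmentLabel = c("unspecified", "proximal",
                                                "distal")) {
  stopifnot(is(seg, "SegmentationResult"))
  .check_calibration(micronsPerPixel)
  segmentLabel <- match.arg(segmentLabel)
  a <- micronsPerPixel^2
  .make_record(
    mediaArea = sum(seg@media) * a,
    lumenArea = sum(seg@lumen) * a,
    plaqueArea = plaquePixelCount(seg) * a,
    collagenArea = sum(seg@collagenInPlaque) * a,
    lipidArea = sum(seg@lipid) * a,
    sectionId = sectionId, segmentLabel = segmentLabel)
}

#' Morphometry record from absolute areas
#'
#' Builds a \code{\linkS4class{MorphometryRecord}} directly from measured
#' absolute areas (square microns), e.g. manual free-hand tracings or
#' published per-section values. Collagen and lipid may be \code{NA} when
#' not measured (manual tracing cannot delineate dispersed collagen).
#'
#' @param mediaArea,lumenArea,plaqueArea absolute areas (um^2).
#' @param collagenArea,lipidArea absolute areas or NA.
#' @param sectionId,segmentLabel as in \code{\link{computeMorphometry}}.
#' @return A \code{\linkS4class{MorphometryRecord}}.
#' @export
#' @examples
#' # automatic measurements of one proximal section
#' rec <- morphometryFromAreas(161749, 36900, 283017, 41446, 37317, "prox-1")
#' rec
morphometryFromAreas <- function(mediaArea, lumenArea, plaqueArea,
                                 collagenArea = NA_real_,
                                 lipidArea = NA_real_,
                                 sectionId = "section",
                                 segmentLabel = c("unspecified", "proximal",
                                                  "distal")) {
  segmentLabel <- match.arg(segmentLabel)
  .make_record(mediaArea, lumenArea, plaqueArea,
               as.numeric(collagenArea), as.numeric(lipidArea),
               sectionId, segmentLabel)
}

#' Relative percent difference between automatic and manual morphometry
#'
#' For each compartment measured in both records returns
#' |automatic - manual| / manual x 100. Compartments whose manual value is
#' zero or missing are \code{NA}.
#'
#' @param auto,manual \code{\linkS4class{MorphometryRecord}}s of the same
#'   section.
#' @return Named numeric vector over media, lumen, plaque, collagen,
#'   lipid (percent).
#' @export
#' @examples
#' a <- morphometryFromAreas(161749, 36900, 283017, 41446, 37317)
#' m <- morphometryFromAreas(155723, 38097, 285795, NA, 39553)
#' round(autoManualAgreement(a, m), 2)
autoManualAgreement <- function(auto, manual) {
  stopifnot(is(auto, "MorphometryRecord"), is(manual, "MorphometryRecord"))
  slots <- c(media = "mediaArea", lumen = "lumenArea", plaque = "plaqueArea",
             collagen = "collagenArea", lipid = "lipidArea")
  vapply(slots, function(s) {
    a <- slot(auto, s); m <- slot(manual, s)
    if (is.na(a) || is.na(m) || m == 0) NA_real_ else abs(a - m) / m * 100
  }, numeric(1))
}

.morph_cols <- c("section_id", "segment_label", "media_area_um2",
                 "lumen_area_um2", "plaque_area_um2", "collagen_area_um2",
                 "lipid_area_um2", "total_vessel_area_um2",
                 "relative_media_pct", "relative_lumen_pct",
                 "relative_plaque_pct", "relative_collagen_pct",
                 "relative_lipid_pct")

#' Tabulate morphometry records
#'
#' One row per section with fixed, documented column names:
#' \code{section_id}, \code{segment_label}, the six absolute areas
#' (\code{*_area_um2}, \code{total_vessel_area_um2}) and the five relative
#' parameters (\code{relative_*_pct}).
#'
#' @param records a \code{MorphometryRecord} or list of them.
#' @return A data.frame.
#' @export
morphometryTable <- function(records) {
  if (is(records, "MorphometryRecord")) records <- list(records)
  stopifnot(all(vapply(records, is, logical(1), "MorphometryRecord")))
  rows <- lapply(records, function(r) data.frame(
    section_id = r@sectionId, segment_label = r@segmentLabel,
    media_area_um2 = r@mediaArea, lumen_area_um2 = r@lumenArea,
    plaque_area_um2 = r@plaqueArea, collagen_area_um2 = r@collagenArea,
    lipid_area_um2 = r@lipidArea, total_vessel_area_um2 = r@totalVesselArea,
    relative_media_pct = r@relativeMedia,
    relative_lumen_pct = r@relativeLumen,
    relative_plaque_pct = r@relativePlaque,
    relative_collagen_pct = r@relativeCollagen,
    relative_lipid_pct = r@relativeLipid,
    stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' @rdname morphometryTable
#' @param table a data.frame with the columns of \code{morphometryTable}.
#' @return \code{recordsFromTable}: a list of \code{MorphometryRecord}s.
#' @export
recordsFromTable <- function(table) {
  missing <- setdiff(.morph_cols, names(table))
  if (length(missing))
    stop("missing morphometry columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    .make_record(r$media_area_um2, r$lumen_area_um2, r$plaque_area_um2,
                 r$collagen_area_um2, r$lipid_area_um2,
                 r$section_id, r$segment_label, warnCollagen = FALSE)
  })
}

#' Read / write a morphometry CSV
#'
#' @param records records for \code{writeMorphometryCSV}.
#' @param path CSV file path.
#' @return \code{readMorphometryCSV}: a data.frame;
#'   \code{writeMorphometryCSV}: \code{path}, invisibly.
#' @export
writeMorphometryCSV <- function(records, path) {
  tab <- if (is.data.frame(records)) records else morphometryTable(records)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMorphometryCSV
#' @export
readMorphometryCSV <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
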