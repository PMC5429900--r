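#' @include colorModel.R
NULL

# Evaluate expr with a private RNG stream, restoring the caller's state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Specify a synthetic OMSB-like artery cross-section
#'
#' The defaults describe a mildly eccentric vessel of realistic murine
#' proportions at ~0.5 um/px: two elastic laminae (inner annulus radii
#' 125-128 px, outer 150-154 px) so the media occupies about a third of
#' the vessel, an eccentric lumen (radius 60 px) leaving roughly half the
#' vessel to plaque, with collagen blobs and lipid vacuoles each around
#' 10-12% of the plaque and a lumen well seeded with erythrocytes.
#'
#' @param size image side (pixels).
#' @param center vessel center (row, col); default image center.
#' @param laminaRadii list of c(inner, outer) radii, innermost first.
#' @param laminaBreaks list (one per lamina) of NULL or c(startDeg,
#'   extentDeg): an unpainted arc modelling a broken lamina.
#' @param lumenRadius,lumenOffset lumen disk radius and center offset.
#' @param collagenBlobs,collagenRadius blue blob count and mean radius.
#' @param lipidVacuoles,lipidRadius white vacuole count and mean radius.
#' @param erythrocytes,erythrocyteRadius yellow disks in the lumen.
#' @param entrappedErythrocytes erythrocyte disks scattered in plaque.
#' @param noiseSd per-channel Gaussian noise (8-bit levels; 0 = clean).
#' @param seed RNG seed (integer).
#' @return A \code{\linkS4class{SectionSpec}}.
#' @export
#' @examples
#' sectionSpec(seed = 3, noiseSd = 8)
sectionSpec <- function(size = 400L,
                        center = NULL,
                        laminaRadii = list(c(125, 128), c(150, 154)),
                        laminaBreaks = NULL,
                        lumenRadius = 60,
                        lumenOffset = c(-18, 8),
                        collagenBlobs = 9L,
                        collagenRadius = 12,
                        lipidVacuoles = 8L,
                        lipidRadius = 11,
                        erythrocytes = 45L,
                        erythrocyteRadius = 3,
                        entrappedErythrocytes = 0L,
                        noiseSd = 0,
                        seed = 1L) {
  size <- as.integer(size)
  if (is.null(center)) center <- rep((size + 1) / 2, 2L)
  if (is.null(laminaBreaks))
    laminaBreaks <- vector("list", length(laminaRadii))
  new("SectionSpec",
      size = size, center = as.numeric(center),
      laminaRadii = lapply(laminaRadii, as.numeric),
      laminaBreaks = laminaBreaks,
      lumenRadius = as.numeric(lumenRadius),
      lumenOffset = as.numeric(lumenOffset),
      collagenBlobs = as.integer(collagenBlobs),
      collagenRadius = as.numeric(collagenRadius),
      lipidVacuoles = as.integer(lipidVacuoles),
      lipidRadius = as.numeric(lipidRadius),
      erythrocytes = as.integer(erythrocytes),
      erythrocyteRadius = as.numeric(erythrocyteRadius),
      entrappedErythrocytes = as.integer(entrappedErythrocytes),
      noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

# Paint a disk into an integer label grid (pixel-center rasterization).
.paint_disk <- function(lab, row, col, radius, code) {
  nr <- nrow(lab); nc <- ncol(lab)
  rr <- max(1L, floor(row - radius)):min(nr, ceiling(row + radius))
  cc <- max(1L, floor(col - radius)):min(nc, ceiling(col + radius))
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  sub <- lab[rr, cc, drop = FALSE]
  sub[d2 <= radius^2] <- code
  lab[rr, cc] <- sub
  lab
}

# Sample a blob center uniformly in the plaque annulus such that the whole
# disk (plus margin) lies inside the internal area, outside the lumen, and
# away from previously placed blobs. Returns c(row, col) or NULL.
.place_blob <- function(spec, radius, placed, margin = 3, tries = 200L) {
  inner_r <- spec@laminaRadii[[1L]][1L]
  lum_c <- spec@center + spec@lumenOffset
  for (t in seq_len(tries)) {
    ang <- runif(1, 0, 2 * pi)
    rad <- sqrt(runif(1)) * (inner_r - radius - margin)
    p <- spec@center + rad * c(sin(ang), cos(ang))
    if (sqrt(sum((p - lum_c)^2)) < spec@lumenRadius + radius + margin) next
    ok <- TRUE
    for (q in placed)
      if (sqrt(sum((p - q$center)^2)) < radius + q$radius + margin) {
        ok <- FALSE; break
      }
    if (ok) return(p)
  }
  NULL
}

#' Generate a synthetic section image with exact ground truth
#'
#' Renders the geometry of a \code{\linkS4class{SectionSpec}} with the
#' prototype colors of the configuration: background, lumen and lipid
#' vacuoles white; media and plaque matrix pink; elastic laminae purple
#' (minus any break arc); collagen blobs blue; erythrocytes yellow.
#' Ground-truth masks and pixel areas are recorded before noise is
#' added, and satisfy the segmentation mask algebra exactly. Rendering is
#' deterministic for a fixed spec (the spec's seed drives all placement
#' and noise through a private RNG stream).
#'
#' @param spec a \code{\linkS4class{SectionSpec}}.
#' @param config a \code{\linkS4class{ColorConfig}} providing prototype
#'   colors.
#' @return A list: \code{image} (H x W x 3 array, 8-bit) and \code{truth}
#'   (a \code{\linkS4class{SyntheticGroundTruth}}).
#' @export
#' @examples
#' tr <- generateSection(sectionSpec(seed = 42))
#' tr$truth
generateSection <- function(spec, config = defaultColorConfig()) {
  validObject(spec)
  .with_seed(spec@seed, .generate_section_impl(spec, config))
}

.generate_section_impl <- function(spec, config) {
  n <- spec@size
  ctr <- spec@center
  rows <- seq_len(n); cols <- seq_len(n)
  d2 <- outer((rows - ctr[1])^2, (cols - ctr[2])^2, "+")
  d <- sqrt(d2)
  lum_c <- ctr + spec@lumenOffset
  dl <- sqrt(outer((rows - lum_c[1])^2, (cols - lum_c[2])^2, "+"))

  code <- function(cl) match(cl, STAIN_CLASSES)
  WHITE <- code("WHITE"); PINK <- code("RED_PINK")
  PURPLE <- code("ELASTIC_PURPLE"); BLUE <- code("COLLAGEN_BLUE")
  YELLOW <- code("ERYTHROCYTE_YELLOW")

  outer_out <- spec@laminaRadii[[length(spec@laminaRadii)]][2L]
  inner_in <- spec@laminaRadii[[1L]][1L]

  lab <- matrix(WHITE, n, n)
  lab[d <= outer_out] <- PINK
  lumen_mask <- dl <= spec@lumenRadius
  lab[lumen_mask] <- WHITE

  # collagen blobs then lipid vacuoles, mutually non-overlapping
  placed <- list()
  sizes <- function(k, mean_r) pmax(4, rnorm(k, mean_r, mean_r / 6))
  for (r in sizes(spec@collagenBlobs, spec@collagenRadius)) {
    p <- .place_blob(spec, r, placed)
    if (is.null(p)) next
    placed[[length(placed) + 1L]] <- list(center = p, radius = r, code = BLUE)
  }
  n_collagen <- length(placed)
  for (r in sizes(spec@lipidVacuoles, spec@lipidRadius)) {
    p <- .place_blob(spec, r, placed)
    if (is.null(p)) next
    placed[[length(placed) + 1L]] <- list(center = p, radius = r, code = WHITE)
  }
  for (b in placed) lab <- .paint_disk(lab, b$center[1], b$center[2],
                                       b$radius, b$code)

  # elastic laminae (possibly broken); angle measured from the +col axis
  theta <- atan2(outer(rows - ctr[1], rep(1, n)),
                 outer(rep(1, n), cols - ctr[2])) * 180 / pi
  theta <- (theta + 360) %% 360
  for (k in seq_along(spec@laminaRadii)) {
    r <- spec@laminaRadii[[k]]
    ring <- d >= r[1] & d <= r[2]
    brk <- spec@laminaBreaks[[k]]
    if (!is.null(brk) && brk[2] > 0) {
      a0 <- brk[1] %% 360; a1 <- (brk[1] + brk[2]) %% 360
      in_arc <- if (a0 <= a1) theta >= a0 & theta < a1
                else theta >= a0 | theta < a1
      ring <- ring & !in_arc
    }
    lab[ring] <- PURPLE
  }

  # erythrocytes in the lumen
  if (spec@erythrocytes > 0L) {
    maxr <- spec@lumenRadius - spec@erythrocyteRadius - 1
    for (i in seq_len(spec@erythrocytes)) {
      ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * maxr
      p <- lum_c + rad * c(sin(ang), cos(ang))
      lab <- .paint_disk(lab, p[1], p[2], spec@erythrocyteRadius, YELLOW)
    }
  }
  # entrapped erythrocytes in the plaque matrix (intraplaque hemorrhage)
  if (spec@entrappedErythrocytes > 0L) {
    for (i in seq_len(spec@entrappedErythrocytes)) {
      p <- .place_blob(spec, spec@erythrocyteRadius, placed, margin = 4)
      if (is.null(p)) next
      placed[[length(placed) + 1L]] <- list(center = p,
                                            radius = spec@erythrocyteRadius,
                                            code = YELLOW)
      lab <- .paint_disk(lab, p[1], p[2], spec@erythrocyteRadius, YELLOW)
    }
  }

  # ground truth from geometry and the painted grid (pre-noise)
  internal <- d < inner_in
  media <- (d <= outer_out) & !internal
  lipid <- lab == WHITE & internal & !lumen_mask
  collagen <- lab == BLUE & internal & !lumen_mask
  areas <- c(media = sum(media), internal = sum(internal),
             lumen = sum(lumen_mask),
             plaque = sum(internal) - sum(lumen_mask),
             lipid = sum(lipid), collagen = sum(collagen))
  truth <- new("SyntheticGroundTruth",
               media = media, internal = internal, lumen = lumen_mask,
               lipid = lipid, collagen = collagen,
               areasPx = stats::setNames(as.numeric(areas), names(areas)),
               spec = spec)

  # render: prototype colors, then optional Gaussian color noise
  proto <- config@prototypes
  img <- array(0L, c(n, n, 3L))
  for (ch in 1:3) {
    pal <- rep(255L, length(STAIN_CLASSES))
    for (cl in rownames(proto)) pal[match(cl, STAIN_CLASSES)] <- proto[cl, ch]
    img[, , ch] <- matrix(pal[lab], n, n)
  }
  if (spec@noiseSd > 0) {
    img <- img + array(rnorm(length(img), 0, spec@noiseSd), dim(img))
    img <- round(pmin(pmax(img, 0), 255))
  }
  storage.mode(img) <- "integer"
  list(image = img, truth = truth)
}

#' Generate a two-group cohort of synthetic sections
#'
#' Draws per-section geometry from documented distributions (outer vessel
#' radius ~ N(150, 6) px clipped to [130, 172]; innermost lamina inner
#' radius ~ 0.82 x outer + N(0, 3); lumen radius ~ 0.48 x inner with 10%
#' log-normal scatter; Poisson blob counts) and applies multiplicative
#' effects to the second ("distal"-like) group. Supported effect names:
#' \code{plaque}, \code{lumen}, \code{media} (area multipliers realised by
#' adjusting the radii analytically, e.g. a plaque effect moves the inner
#' lamina outward at fixed lumen and media area) and \code{collagen},
#' \code{lipid} (blob count multipliers). Per-section seeds are drawn once
#' from the cohort seed, so any one section can be regenerated
#' independently.
#'
#' @param nPerGroup sections per group (>= 1).
#' @param groupEffects named numeric vector of multiplicative shifts for
#'   group 2, e.g. \code{c(plaque = 1.2)}; empty for identical groups.
#' @param seed cohort seed.
#' @param render if TRUE each entry carries the rendered image; FALSE
#'   (default) keeps only ground truth, which is what cohort-level
#'   statistics consume.
#' @param noiseSd per-channel noise for rendered images.
#' @return A list of entries: \code{spec}, \code{truth}, \code{group}
#'   (\code{"proximal"}/\code{"distal"}), \code{image} (or NULL).
#' @export
#' @examples
#' coh <- generateCohort(3, c(plaque = 1.2), seed = 1)
#' sapply(coh, function(s) s$truth@areasPx[["plaque"]])
generateCohort <- function(nPerGroup, groupEffects = numeric(0), seed = 1L,
                           render = FALSE, noiseSd = 0) {
  stopifnot(nPerGroup >= 1)
  known <- c("plaque", "lumen", "media", "collagen", "lipid")
  if (length(groupEffects) && !all(names(groupEffects) %in% known))
    stop("unknown effect name(s): ",
         paste(setdiff(names(groupEffects), known), collapse = ", "),
         call. = FALSE)
  eff <- function(p) if (p %in% names(groupEffects)) groupEffects[[p]] else 1
  ntot <- 2L * nPerGroup
  seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, ntot))
  groups <- rep(c("proximal", "distal"), each = nPerGroup)

  out <- vector("list", ntot)
  for (i in seq_len(ntot)) {
    distal <- groups[i] == "distal"
    spec <- .with_seed(seeds[i], {
      outer_out <- min(172, max(130, rnorm(1, 150, 6)))
      inner_in <- min(outer_out - 10, 0.82 * outer_out + rnorm(1, 0, 3))
      lumen_r <- 0.48 * inner_in * exp(rnorm(1, 0, 0.1))
      if (distal) {
        lumen_r <- lumen_r * sqrt(eff("lumen"))
        # plaque effect: move the inner lamina outward at fixed lumen
        media_area <- outer_out^2 - inner_in^2
        inner_in <- sqrt(lumen_r^2 + eff("plaque") * (inner_in^2 - lumen_r^2))
        outer_out <- sqrt(inner_in^2 + eff("media") * media_area)
      }
      off_ang <- runif(1, 0, 2 * pi)
      off_len <- runif(1, 0, 0.25) * (inner_in - lumen_r - 4)
      ncol_blobs <- rpois(1, 9 * if (distal) eff("collagen") else 1)
      nlip <- rpois(1, 8 * if (distal) eff("lipid") else 1)
      size <- 2L * as.integer(ceiling(outer_out + 6))
      sectionSpec(
        size = size,
        laminaRadii = list(c(inner_in, inner_in + 3),
                           c(outer_out - 4, outer_out)),
        lumenRadius = lumen_r,
        lumenOffset = off_len * c(sin(off_ang), cos(off_ang)),
        collagenBlobs = ncol_blobs,
        lipidVacuoles = nlip,
        erythrocytes = rpois(1, 45),
        noiseSd = noiseSd,
        seed = seeds[i])
    })
    tr <- generateSection(spec)
    out[[i]] <- list(spec = spec, truth = tr$truth, group = groups[i],
                     image = if (render) tr$image else NULL)
  }
  out
}

#' Morphometry records from cohort ground truth
#'
#' Converts the exact ground-truth areas of a generated cohort into
#' \code{\linkS4class{MorphometryRecord}}s (pixel counts times the square
#' of the calibration), carrying each section's group label -- the input
#' \code{\link{compareSegments}} expects.
#'
#' @param cohort list from \code{\link{generateCohort}}.
#' @param micronsPerPixel spatial calibration (default 0.5 um/px).
#' @return List of \code{MorphometryRecord}s.
#' @export
cohortRecords <- function(cohort, micronsPerPixel = 0.5) {
  .check_calibration(micronsPerPixel)
  a <- micronsPerPixel^2
  lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    px <- s$truth@areasPx
    .make_record(px[["media"]] * a, px[["lumen"]] * a, px[["plaque"]] * a,
                 px[["collagen"]] * a, px[["lipid"]] * a,
                 sectionId = sprintf("%s-%03d", s$group, i),
                 segmentLabel = s$group)
  })
}
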