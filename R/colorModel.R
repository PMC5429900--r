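#' @include AllClasses.R
NULL

# Default hue sectors for the named stain colors. Order = priority among the
# chromatic classes (relevant only if a user config makes sectors overlap;
# the defaults tile the circle without overlap).
.default_hue_ranges <- function() {
  m <- rbind(
    ERYTHROCYTE_YELLOW = c(40, 70),
    COLLAGEN_BLUE      = c(190, 260),
    ELASTIC_PURPLE     = c(260, 320),
    RED_PINK           = c(320, 40)   # wraps through 0
  )
  colnames(m) <- c("low", "high")
  m
}

.default_prototypes <- function() {
  m <- rbind(
    ELASTIC_PURPLE     = c(150L, 60L, 170L),  # hue ~289
    COLLAGEN_BLUE      = c(40L, 70L, 200L),   # hue ~229
    ERYTHROCYTE_YELLOW = c(230L, 200L, 30L),  # hue ~51
    RED_PINK           = c(230L, 120L, 140L), # hue ~349
    WHITE              = c(255L, 255L, 255L)
  )
  colnames(m) <- c("red", "green", "blue")
  m
}

#' Default HSV color configuration for OMSB-stained sections
#'
#' Named stain colors are mapped to conventional hue sectors: yellow
#' (erythrocytes) 40-70 deg, blue (collagen) 190-260, purple (elastica and
#' other orcein-positive material) 260-320, red/pink (muscle, fibrin,
#' nuclei) 320-40 wrapping through 0. WHITE is any pixel with HSV value
#' >= 0.85 and saturation <= 0.15 and is decided before the hue classes
#' (hue is meaningless at low saturation). Pixels below the chroma gates
#' (saturation or value < 0.15) that are not WHITE become OTHER. All
#' thresholds are user-overridable, by argument or via a YAML config file.
#'
#' @param whiteMinValue,whiteMaxSaturation the WHITE rule (fractions).
#' @param hueRanges 4x2 matrix of hue sectors in degrees, rows
#'   \code{ERYTHROCYTE_YELLOW}, \code{COLLAGEN_BLUE}, \code{ELASTIC_PURPLE},
#'   \code{RED_PINK}; a row with low > high wraps modulo 360.
#' @param minSaturation,minValue chroma gates for the chromatic classes.
#' @param prototypes 5x3 RGB matrix of per-class prototype colors.
#' @return A \code{\linkS4class{ColorConfig}}.
#' @seealso \code{\link{classifyPixels}}, \code{\link{readColorConfig}}
#' @export
#' @examples
#' cfg <- defaultColorConfig()
#' cfg
defaultColorConfig <- function(whiteMinValue = 0.85,
                               whiteMaxSaturation = 0.15,
                               hueRanges = .default_hue_ranges(),
                               minSaturation = 0.15,
                               minValue = 0.15,
                               prototypes = .default_prototypes()) {
  new("ColorConfig",
      whiteMinValue = whiteMinValue,
      whiteMaxSaturation = whiteMaxSaturation,
      hueRanges = hueRanges,
      minSaturation = minSaturation,
      minValue = minValue,
      prototypes = prototypes)
}

#' Prototype RGB colors of a configuration
#'
#' @param config a \code{\linkS4class{ColorConfig}}.
#' @return 5x3 integer matrix of 8-bit RGB rows named by stain class.
#' @export
prototypeColors <- function(config = defaultColorConfig()) config@prototypes

.check_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop("image must be an H x W x 3 RGB array", call. = FALSE)
  v <- image[, , 1:3]
  if (anyNA(v) || min(v) < 0 || max(v) > 255 || any(v != round(v)))
    stop("image must hold 8-bit channel values (integers in 0..255); ",
         "use readSectionImage() to load files", call. = FALSE)
  invisible(TRUE)
}

.hue_in_range <- function(h, lo, hi) {
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}

#' Classify every pixel of an RGB image into stain classes
#'
#' Converts the image to HSV and applies, per pixel and without spatial
#' context, the priority rule of the configuration: WHITE first (value and
#' saturation rule), then the chromatic hue sectors in the order of
#' \code{config@hueRanges} (yellow, blue, purple, red/pink by default),
#' then OTHER. The result is a partition: every pixel gets exactly one
#' label. The purple class deliberately pools everything orcein-positive
#' (elastic fibers, nuclei, fibrin, foam cells); separating laminae from
#' blobs is geometric and happens in \code{\link{detectLaminae}}.
#'
#' @param image H x W x 3 array of 8-bit RGB values (0-255); an alpha
#'   channel, if present, is ignored.
#' @param config a \code{\linkS4class{ColorConfig}}.
#' @return A \code{\linkS4class{ClassMap}}.
#' @export
#' @examples
#' img <- array(0L, c(2, 2, 3))
#' img[1, 1, ] <- c(30L, 40L, 200L)   # blue
#' img[1, 2, ] <- c(255L, 255L, 255L) # white
#' classCounts(classifyPixels(img))
classifyPixels <- function(image, config = defaultColorConfig()) {
  .check_rgb_image(image)
  validObject(config)
  h <- dim(image)[1]; w <- dim(image)[2]
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  hue <- hsv[1, ] * 360
  sat <- hsv[2, ]
  val <- hsv[3, ]

  lab <- rep.int(match("OTHER", STAIN_CLASSES), h * w)
  chromatic_ok <- sat >= config@minSaturation & val >= config@minValue
  # lowest priority first, so later (higher-priority) assignments overwrite
  hr <- config@hueRanges
  for (cl in rev(rownames(hr))) {
    sel <- chromatic_ok & .hue_in_range(hue, hr[cl, 1], hr[cl, 2])
    lab[sel] <- match(cl, STAIN_CLASSES)
  }
  white <- val >= config@whiteMinValue & sat <= config@whiteMaxSaturation
  lab[white] <- match("WHITE", STAIN_CLASSES)

  new("ClassMap", labels = matrix(as.integer(lab), h, w),
      classes = STAIN_CLASSES)
}

#' Binary mask of one stain class
#'
#' @param classmap a \code{\linkS4class{ClassMap}}.
#' @param label one of \code{\link{stainClasses}()}.
#' @return Logical matrix, TRUE where the pixel carries \code{label}.
#' @export
#' @examples
#' img <- array(255L, c(4, 4, 3))
#' classMask(classifyPixels(img), "WHITE")
classMask <- function(classmap, label) {
  stopifnot(is(classmap, "ClassMap"))
  code <- match(label, classmap@classes)
  if (is.na(code)) stop("unknown stain class: ", label, call. = FALSE)
  classmap@labels == code
}

#' Per-class pixel counts of a class map
#'
#' The counts always sum to the number of pixels (partition property).
#'
#' @param classmap a \code{\linkS4class{ClassMap}}.
#' @return Named integer vector over \code{\link{stainClasses}()}.
#' @export
classCounts <- function(classmap) {
  stopifnot(is(classmap, "ClassMap"))
  cnt <- tabulate(classmap@labels, nbins = length(classmap@classes))
  names(cnt) <- classmap@classes
  cnt
}

#' Read / write a color configuration as YAML
#'
#' The file exposes every threshold by name under a \code{color:} block
#' (see \code{system.file("extdata", "default-config.yaml", package =
#' "plaquemorph")} for a committed example). Missing keys fall back to
#' the defaults of \code{\link{defaultColorConfig}}.
#'
#' @param path file path.
#' @param config a \code{\linkS4class{ColorConfig}} (for writing).
#' @return \code{readColorConfig} returns a \code{ColorConfig};
#'   \code{writeColorConfig} returns \code{path} invisibly.
#' @export
readColorConfig <- function(path) {
  y <- yaml::read_yaml(path)
  colorConfigFromList(if (!is.null(y$color)) y$color else y)
}

#' @rdname readColorConfig
#' @export
writeColorConfig <- function(config, path) {
  yaml::write_yaml(list(color = colorConfigAsList(config)), path)
  invisible(path)
}

#' @rdname readColorConfig
#' @export
colorConfigAsList <- function(config) {
  hr <- config@hueRanges
  pr <- config@prototypes
  list(
    white_min_value = config@whiteMinValue,
    white_max_saturation = config@whiteMaxSaturation,
    min_saturation = config@minSaturation,
    min_value = config@minValue,
    hue_ranges = stats::setNames(
      lapply(rownames(hr), function(cl) as.numeric(hr[cl, ])), rownames(hr)),
    prototypes = stats::setNames(
      lapply(rownames(pr), function(cl) as.integer(pr[cl, ])), rownames(pr))
  )
}

#' @rdname readColorConfig
#' @param x a named list as produced by \code{colorConfigAsList}.
#' @export
colorConfigFromList <- function(x) {
  d <- defaultColorConfig()
  hr <- d@hueRanges
  for (cl in names(x$hue_ranges)) {
    if (!cl %in% rownames(hr))
      stop("unknown chromatic class in config: ", cl, call. = FALSE)
    hr[cl, ] <- as.numeric(x$hue_ranges[[cl]])
  }
  pr <- d@prototypes
  for (cl in names(x$prototypes)) pr[cl, ] <- as.integer(x$prototypes[[cl]])
  defaultColorConfig(
    whiteMinValue = x$white_min_value %||% d@whiteMinValue,
    whiteMaxSaturation = x$white_max_saturation %||% d@whiteMaxSaturation,
    hueRanges = hr,
    minSaturation = x$min_saturation %||% d@minSaturation,
    minValue = x$min_value %||% d@minValue,
    prototypes = pr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
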