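#' @import methods
NULL

setClassUnion("FrameMetaOrNULL", "NULL")

#' Metadata for one photograph in a dual-view time-lapse series
#'
#' Each plant is photographed from two fixed cameras (one directly above,
#' one at soil level) at regular intervals. A \code{FrameMeta} records which
#' plant, which view, and when, plus the file location.
#'
#' @slot plantId character(1), plant label parsed from the filename.
#' @slot view character(1), either \code{"top"} or \code{"side"}.
#' @slot timestampMin numeric(1), minutes since the start of the series
#'   (non-negative).
#' @slot path character(1), file path (may be \code{NA} for in-memory
#'   frames).
#' @export
setClass("FrameMeta",
  representation(plantId = "character", view = "character",
                 timestampMin = "numeric", path = "character"),
  prototype(plantId = NA_character_, view = "top", timestampMin = 0,
            path = NA_character_))

setValidity("FrameMeta", function(object) {
  msg <- character(0)
  if (length(object@view) != 1L || !object@view %in% c("top", "side"))
    msg <- c(msg, "'view' must be exactly \"top\" or \"side\"")
  if (length(object@timestampMin) != 1L || is.na(object@timestampMin) ||
      object@timestampMin < 0)
    msg <- c(msg, "'timestampMin' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

setIs("FrameMeta", "FrameMetaOrNULL")

#' Construct frame metadata
#'
#' @param plantId plant label.
#' @param view \code{"top"} or \code{"side"}.
#' @param timestampMin minutes since series start.
#' @param path optional source file path.
#' @return A \linkS4class{FrameMeta} object.
#' @examples
#' FrameMeta("p07", "top", 600)
#' @export
FrameMeta <- function(plantId, view, timestampMin, path = NA_character_) {
  new("FrameMeta", plantId = as.character(plantId),
      view = as.character(view),
      timestampMin = as.numeric(timestampMin), path = as.character(path))
}

#' One photograph with its metadata
#'
#' Pixels are stored as an H x W x 3 numeric array with channel values in
#' [0, 1] (the convention of \pkg{png} and \pkg{EBImage}); row 1 is the top
#' image row. Grayscale sources are promoted to RGB by channel replication
#' on load.
#'
#' @slot meta a \linkS4class{FrameMeta}.
#' @slot pixels numeric array, H x W x 3, values in [0, 1].
#' @export
setClass("Frame",
  representation(meta = "FrameMeta", pixels = "array"))

setValidity("Frame", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("'pixels' must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L)
    return("frame must have at least one row and one column")
  rng <- range(object@pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1)
    return("channel values must lie in [0, 1]")
  TRUE
})

#' Construct a Frame from a pixel array
#'
#' @param pixels H x W x 3 numeric array in [0, 1], or an H x W matrix
#'   (promoted to RGB by replication).
#' @param meta a \linkS4class{FrameMeta}; a placeholder is supplied if
#'   omitted.
#' @return A \linkS4class{Frame}.
#' @export
Frame <- function(pixels, meta = FrameMeta("unknown", "top", 0)) {
  if (is.matrix(pixels))
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  new("Frame", meta = meta, pixels = pixels)
}

#' Index of a dual-view time-lapse series
#'
#' Groups every parseable image in a directory by (plant, timestamp). An
#' entry is complete when both the top and the side view are present;
#' incomplete entries are listed, never silently dropped.
#'
#' @slot plants character vector of plant ids present.
#' @slot timepoints sorted numeric vector of timestamps (minutes).
#' @slot pairs named list; each element \code{list(top =, side =)} of
#'   \linkS4class{FrameMeta}, keyed \code{"<plant>@<minutes>"}.
#' @slot incomplete data.frame of (plant_id, timestamp_min, missing_view).
#' @slot issues character vector of per-file problems (unparseable names,
#'   off-grid timestamps).
#' @export
setClass("SeriesIndex",
  representation(plants = "character", timepoints = "numeric",
                 pairs = "list", incomplete = "data.frame",
                 issues = "character"))

setValidity("SeriesIndex", function(object) {
  ok <- vapply(object@pairs, function(p)
    identical(sort(names(p)), c("side", "top")), logical(1))
  if (length(ok) && !all(ok))
    return("every complete pair must hold exactly one 'top' and one 'side' frame")
  TRUE
})

#' Segmentation parameters
#'
#' The per-series constants of the plant-extraction step: a threshold on
#' the vegetation-index scale, an index clipping ceiling, a minimum object
#' area, and an optional rectangular region of interest. They mirror the
#' once-per-experiment tuning a user performs on an exemplary image and are
#' then held fixed across the whole time course.
#'
#' @slot threshold numeric(1), on the excess-green scale ([-2, 2] for
#'   channels in [0, 1]).
#' @slot maxValue numeric(1), index values are clipped to this ceiling
#'   before thresholding; must exceed \code{threshold}.
#' @slot size integer(1), 8-connected components smaller than this many
#'   pixels are discarded.
#' @slot roi integer(4) \code{c(row0, col0, height, width)} (1-based,
#'   inclusive origin) or \code{integer(0)} for the whole frame.
#' @export
setClass("SegmentationParams",
  representation(threshold = "numeric", maxValue = "numeric",
                 size = "integer", roi = "integer"),
  prototype(threshold = 0.5, maxValue = 2, size = 50L, roi = integer(0)))

setValidity("SegmentationParams", function(object) {
  msg <- character(0)
  if (object@size < 0L) msg <- c(msg, "'size' must be >= 0")
  if (!(length(object@roi) %in% c(0L, 4L)))
    msg <- c(msg, "'roi' must be integer(4) c(row0, col0, height, width) or empty")
  if (length(object@roi) == 4L && any(object@roi[3:4] < 1L))
    msg <- c(msg, "'roi' height and width must be >= 1")
  if (object@threshold >= object@maxValue)
    msg <- c(msg, "'threshold' must be strictly less than 'maxValue'")
  if (length(msg)) msg else TRUE
})

#' Construct segmentation parameters
#'
#' @param threshold threshold on the vegetation-index scale.
#' @param maxValue clipping ceiling for the index (must exceed
#'   \code{threshold}).
#' @param size minimum component area in pixels.
#' @param roi optional \code{c(row0, col0, height, width)} region of
#'   interest, 1-based.
#' @return A \linkS4class{SegmentationParams}.
#' @examples
#' SegmentationParams(threshold = 0.5, size = 50)
#' @export
SegmentationParams <- function(threshold = 0.5, maxValue = 2, size = 50L,
                               roi = NULL) {
  new("SegmentationParams", threshold = as.numeric(threshold),
      maxValue = as.numeric(maxValue), size = as.integer(size),
      roi = if (is.null(roi)) integer(0) else as.integer(roi))
}

#' Binary plant mask
#'
#' A boolean plant/background grid with the same dimensions as the frame
#' it was derived from. \code{flags} records non-fatal conditions (an empty
#' segmentation, a degenerate shape) so callers can skip a time point
#' without aborting a batch.
#'
#' @slot mask logical matrix, H x W.
#' @slot meta the source \linkS4class{FrameMeta}, or \code{NULL}.
#' @slot flags character vector of condition labels.
#' @export
setClass("BinaryMask",
  representation(mask = "matrix", meta = "FrameMetaOrNULL",
                 flags = "character"),
  prototype(flags = character(0), meta = NULL))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@mask)) return("'mask' must be a logical matrix")
  TRUE
})

#' Construct a BinaryMask
#'
#' @param mask logical matrix.
#' @param meta optional source \linkS4class{FrameMeta}.
#' @param flags character vector of condition labels.
#' @return A \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(mask, meta = NULL, flags = character(0)) {
  storage.mode(mask) <- "logical"
  new("BinaryMask", mask = mask, meta = meta, flags = flags)
}

#' Central moments of a binary mask
#'
#' Pixel centers sit at integer coordinates; moments are central and
#' normalized by the pixel count, so they are invariant to translation and
#' to the index origin. \code{mu20} carries the exponent on the row
#' coordinate, \code{mu02} on the column coordinate.
#'
#' @slot n integer(1), pixel count.
#' @slot centroid numeric(2), (row, col) of the centroid.
#' @slot mu20,mu02,mu11 second central moments (px^2), normalized by n.
#' @export
setClass("MaskMoments",
  representation(n = "integer", centroid = "numeric", mu20 = "numeric",
                 mu02 = "numeric", mu11 = "numeric"))

setValidity("MaskMoments", function(object) {
  msg <- character(0)
  if (object@n < 1L) msg <- c(msg, "'n' must be >= 1")
  if (object@mu20 < 0 || object@mu02 < 0)
    msg <- c(msg, "diagonal moments must be non-negative")
  # covariance matrix must be positive semi-definite; allow fp slack
  det <- object@mu20 * object@mu02 - object@mu11^2
  if (det < -1e-8 * max(1, object@mu20 * object@mu02))
    msg <- c(msg, "moment matrix must be positive semi-definite")
  if (length(msg)) msg else TRUE
})

#' Equal-moment ellipse of a rosette silhouette
#'
#' The ellipse whose second-order central moments equal those of the mask;
#' its full axis lengths are four times the square roots of the eigenvalues
#' of the coordinate covariance matrix, so a filled disc of radius R yields
#' major = minor = 2R exactly in the continuum limit.
#'
#' @slot centroid numeric(2), (row, col).
#' @slot majorAxisPx,minorAxisPx full axis lengths in pixels,
#'   \code{majorAxisPx >= minorAxisPx >= 0}.
#' @slot orientationRad angle of the major axis against the column axis
#'   (counter-clockwise with the row axis pointing up), in (-pi/2, pi/2].
#' @slot degenerate logical(1), \code{TRUE} when the mask is collinear
#'   (minor axis 0).
#' @export
setClass("EllipseFit",
  representation(centroid = "numeric", majorAxisPx = "numeric",
                 minorAxisPx = "numeric", orientationRad = "numeric",
                 degenerate = "logical"),
  prototype(degenerate = FALSE))

setValidity("EllipseFit", function(object) {
  if (object@minorAxisPx < 0 ||
      object@majorAxisPx < object@minorAxisPx - 1e-9)
    return("axes must satisfy major >= minor >= 0")
  TRUE
})

#' Plant height above the soil reference line
#'
#' Height is measured on the side view as the row distance between the
#' highest plant pixel and a fixed soil reference row (rows increase
#' downward).
#'
#' @slot heightPx numeric(1), \code{max(0, linePosition - topRow)}.
#' @slot topRow numeric(1), row index of the highest mask pixel considered
#'   (\code{NA} when none lies above the line and clipping is on).
#' @slot linePosition numeric(1), soil reference row.
#' @slot flagged logical(1), \code{TRUE} when the mask lies entirely at or
#'   below the line.
#' @export
setClass("HeightMeasurement",
  representation(heightPx = "numeric", topRow = "numeric",
                 linePosition = "numeric", flagged = "logical"),
  prototype(flagged = FALSE))

setValidity("HeightMeasurement", function(object) {
  if (object@heightPx < 0) return("'heightPx' must be >= 0")
  TRUE
})

#' Per-camera pixel-to-millimetre calibration
#'
#' Conversion factors derived from a length standard photographed by each
#' camera (see \code{\link{calibrate}}).
#'
#' @slot mmPerPxTop,mmPerPxSide numeric(1), strictly positive and finite.
#' @export
setClass("Calibration",
  representation(mmPerPxTop = "numeric", mmPerPxSide = "numeric"))

setValidity("Calibration", function(object) {
  bad <- function(x) length(x) != 1L || !is.finite(x) || x <= 0
  if (bad(object@mmPerPxTop) || bad(object@mmPerPxSide))
    return("calibration factors must be single, finite, strictly positive numbers")
  TRUE
})

#' Construct a Calibration
#'
#' @param mmPerPxTop mm per pixel for the top-view camera.
#' @param mmPerPxSide mm per pixel for the side-view camera.
#' @return A \linkS4class{Calibration}.
#' @export
Calibration <- function(mmPerPxTop, mmPerPxSide = mmPerPxTop) {
  new("Calibration", mmPerPxTop = as.numeric(mmPerPxTop),
      mmPerPxSide = as.numeric(mmPerPxSide))
}

#' Parameters of a synthetic dual-view scene
#'
#' The renderer treats the plant as a cylinder of leaf length L and
#' elevation angle theta: the top silhouette is a filled ellipse with
#' semi-major axis L cos(theta) (scaled by the eccentricity for the minor
#' axis), the side silhouette an isoceles triangle whose apex sits
#' L sin(theta) above the soil row. All ground-truth fields follow from
#' these formulas exactly.
#'
#' @slot leafLengthMm numeric(1), leaf length L in mm (> 0).
#' @slot elevationDeg numeric(1), elevation angle theta in [0, 90).
#' @slot eccentricity numeric(1), minor/major ratio of the top silhouette,
#'   in (0, 1].
#' @slot mmPerPxTop,mmPerPxSide numeric(1), rendering scale per view.
#' @slot topDim,sideDim integer(2), image height and width per view.
#' @slot soilRow integer(1), soil reference row of the side view.
#' @slot rotationDeg numeric(1), rotation of the top-view ellipse.
#' @slot plantRgb,backgroundRgb numeric(3) colors in [0, 1].
#' @slot noiseSd numeric(1), per-channel Gaussian noise sd in [0, 0.2].
#' @slot seed numeric(1), RNG seed for the noise (\code{NA} draws from the
#'   current RNG stream).
#' @export
setClass("SceneParams",
  representation(leafLengthMm = "numeric", elevationDeg = "numeric",
                 eccentricity = "numeric", mmPerPxTop = "numeric",
                 mmPerPxSide = "numeric", topDim = "integer",
                 sideDim = "integer", soilRow = "integer",
                 rotationDeg = "numeric", plantRgb = "numeric",
                 backgroundRgb = "numeric", noiseSd = "numeric",
                 seed = "numeric"))

setValidity("SceneParams", function(object) {
  msg <- character(0)
  if (object@leafLengthMm <= 0) msg <- c(msg, "'leafLengthMm' must be > 0")
  if (object@elevationDeg < 0 || object@elevationDeg >= 90)
    msg <- c(msg, "'elevationDeg' must lie in [0, 90)")
  if (object@eccentricity <= 0 || object@eccentricity > 1)
    msg <- c(msg, "'eccentricity' must lie in (0, 1]")
  if (object@mmPerPxTop <= 0 || object@mmPerPxSide <= 0)
    msg <- c(msg, "pixel scales must be > 0")
  if (object@noiseSd < 0 || object@noiseSd > 0.2)
    msg <- c(msg, "'noiseSd' must lie in [0, 0.2]")
  if (object@soilRow < 1L || object@soilRow > object@sideDim[1])
    msg <- c(msg, "'soilRow' must lie within the side image")
  if (any(c(object@plantRgb, object@backgroundRgb) < 0) ||
      any(c(object@plantRgb, object@backgroundRgb) > 1))
    msg <- c(msg, "colors must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct scene parameters
#'
#' Defaults render a mid-sized Arabidopsis-like rosette (leaf length 20 mm)
#' at 0.15 mm/px in 280 x 280 frames, hard-edged (no noise).
#'
#' @param leafLengthMm leaf length L in mm.
#' @param elevationDeg elevation angle theta in degrees, [0, 90).
#' @param eccentricity minor/major axis ratio of the top silhouette.
#' @param mmPerPxTop,mmPerPxSide rendering scale, mm per pixel.
#' @param topDim,sideDim image dimensions c(height, width).
#' @param soilRow soil reference row of the side view.
#' @param rotationDeg rotation of the top-view ellipse, degrees
#'   counter-clockwise.
#' @param plantRgb,backgroundRgb RGB colors in [0, 1].
#' @param noiseSd per-channel Gaussian noise sd (on the [0, 1] scale).
#' @param seed RNG seed for the noise; \code{NA} uses the current stream.
#' @return A \linkS4class{SceneParams}.
#' @examples
#' SceneParams(leafLengthMm = 20, elevationDeg = 45)
#' @export
SceneParams <- function(leafLengthMm = 20, elevationDeg = 45,
                        eccentricity = 1, mmPerPxTop = 0.15,
                        mmPerPxSide = 0.15, topDim = c(280L, 280L),
                        sideDim = c(280L, 280L), soilRow = 240L,
                        rotationDeg = 0,
                        plantRgb = c(0.10, 0.78, 0.12),
                        backgroundRgb = c(0.06, 0.05, 0.04),
                        noiseSd = 0, seed = NA_real_) {
  new("SceneParams", leafLengthMm = as.numeric(leafLengthMm),
      elevationDeg = as.numeric(elevationDeg),
      eccentricity = as.numeric(eccentricity),
      mmPerPxTop = as.numeric(mmPerPxTop),
      mmPerPxSide = as.numeric(mmPerPxSide),
      topDim = as.integer(topDim), sideDim = as.integer(sideDim),
      soilRow = as.integer(soilRow), rotationDeg = as.numeric(rotationDeg),
      plantRgb = as.numeric(plantRgb),
      backgroundRgb = as.numeric(backgroundRgb),
      noiseSd = as.numeric(noiseSd), seed = as.numeric(seed))
}

#' Ground truth of a rendered scene
#'
#' @slot rTrueMm cylinder radius, \code{L cos(theta) (1 + e) / 2} mm.
#' @slot hTrueMm cylinder height, \code{L sin(theta)} mm.
#' @slot leiTrueDeg \code{atan(h/r) * 180 / pi}; equals theta exactly when
#'   the rosette is circular (e = 1).
#' @slot topPxCount,sidePxCount rendered silhouette pixel counts.
#' @export
setClass("SceneTruth",
  representation(rTrueMm = "numeric", hTrueMm = "numeric",
                 leiTrueDeg = "numeric", topPxCount = "integer",
                 sidePxCount = "integer"))

setValidity("SceneTruth", function(object) {
  if (object@leiTrueDeg < 0 || object@leiTrueDeg >= 90)
    return("'leiTrueDeg' must lie in [0, 90)")
  TRUE
})

#' Leaf elevation response model for the simulator
#'
#' Per-plant leaf elevation index trajectories are drawn as
#' \deqn{LEI_i(t) = baseline + b_i + A \sigma(k (t - t_{50})) D(t) +
#'   osc \sin(2 \pi t / period) + \epsilon_{it}}
#' with \eqn{\sigma} the logistic function, \eqn{D(t) =
#' \exp(-\max(0, t - decayStart)/decayTau)} when a decay is set (else 1),
#' \eqn{b_i \sim N(0, plantSd^2)} a between-plant offset and
#' \eqn{\epsilon \sim N(0, frameSd^2)} frame-to-frame noise. Values are
#' clipped to [0, 89] degrees.
#'
#' @slot baselineDeg resting elevation index, degrees.
#' @slot amplitudeDeg A, response amplitude, degrees (>= 0).
#' @slot onsetMin treatment onset, minutes (the normalization reference).
#' @slot halftimeMin t50 of the logistic rise, minutes.
#' @slot riseRatePerMin k, logistic rate, 1/min.
#' @slot oscAmpDeg amplitude of the rhythmic oscillation, degrees.
#' @slot oscPeriodMin oscillation period, minutes (> 0).
#' @slot decayStartMin,decayTauMin transient-response decay (minutes);
#'   \code{decayStartMin = NA} disables the decay.
#' @slot plantSdDeg between-plant sd, degrees.
#' @slot frameSdDeg within-plant frame-to-frame sd, degrees.
#' @export
setClass("ResponseModel",
  representation(baselineDeg = "numeric", amplitudeDeg = "numeric",
                 onsetMin = "numeric", halftimeMin = "numeric",
                 riseRatePerMin = "numeric", oscAmpDeg = "numeric",
                 oscPeriodMin = "numeric", decayStartMin = "numeric",
                 decayTauMin = "numeric", plantSdDeg = "numeric",
                 frameSdDeg = "numeric"))

setValidity("ResponseModel", function(object) {
  msg <- character(0)
  if (object@amplitudeDeg < 0) msg <- c(msg, "'amplitudeDeg' must be >= 0")
  if (object@oscPeriodMin <= 0) msg <- c(msg, "'oscPeriodMin' must be > 0")
  if (!is.na(object@decayStartMin) && object@decayTauMin <= 0)
    msg <- c(msg, "'decayTauMin' must be > 0 when a decay is set")
  if (object@plantSdDeg < 0 || object@frameSdDeg < 0)
    msg <- c(msg, "noise sds must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a response model
#'
#' @param baselineDeg resting elevation index, degrees.
#' @param amplitudeDeg response amplitude A, degrees.
#' @param onsetMin treatment onset, minutes.
#' @param halftimeMin logistic halftime t50, minutes.
#' @param riseRatePerMin logistic rate k, 1/min.
#' @param oscAmpDeg rhythmic oscillation amplitude, degrees.
#' @param oscPeriodMin oscillation period, minutes.
#' @param decayStartMin,decayTauMin transient decay start and time constant
#'   (minutes); \code{decayStartMin = NA} disables the decay.
#' @param plantSdDeg between-plant sd, degrees.
#' @param frameSdDeg frame-to-frame sd, degrees.
#' @return A \linkS4class{ResponseModel}.
#' @seealso \code{\link{responsePreset}} for the shipped genotype presets.
#' @export
ResponseModel <- function(baselineDeg = 22, amplitudeDeg = 25,
                          onsetMin = 0, halftimeMin = 300,
                          riseRatePerMin = 0.015, oscAmpDeg = 1.5,
                          oscPeriodMin = 1440, decayStartMin = NA_real_,
                          decayTauMin = 240, plantSdDeg = 2,
                          frameSdDeg = 0.75) {
  new("ResponseModel", baselineDeg = as.numeric(baselineDeg),
      amplitudeDeg = as.numeric(amplitudeDeg),
      onsetMin = as.numeric(onsetMin),
      halftimeMin = as.numeric(halftimeMin),
      riseRatePerMin = as.numeric(riseRatePerMin),
      oscAmpDeg = as.numeric(oscAmpDeg),
      oscPeriodMin = as.numeric(oscPeriodMin),
      decayStartMin = as.numeric(decayStartMin),
      decayTauMin = as.numeric(decayTauMin),
      plantSdDeg = as.numeric(plantSdDeg),
      frameSdDeg = as.numeric(frameSdDeg))
}

# ---- show methods -----------------------------------------------------------

setMethod("show", "FrameMeta", function(object) {
  cat(sprintf("FrameMeta: plant %s, %s view, t = %g min\n  path: %s\n",
              object@plantId, object@view, object@timestampMin,
              object@path))
})

setMethod("show", "Frame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Frame: %d x %d px, plant %s, %s view, t = %g min\n",
              d[1], d[2], object@meta@plantId, object@meta@view,
              object@meta@timestampMin))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d px, %d foreground px%s\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ", "), "]")
              else ""))
})

setMethod("show", "EllipseFit", function(object) {
  cat(sprintf(paste0("EllipseFit: major %.2f px, minor %.2f px, ",
                     "orientation %.1f deg%s\n"),
              object@majorAxisPx, object@minorAxisPx,
              object@orientationRad * 180 / pi,
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "SeriesIndex", function(object) {
  cat(sprintf(paste0("SeriesIndex: %d plants, %d timepoints, ",
                     "%d complete pairs, %d incomplete\n"),
              length(object@plants), length(object@timepoints),
              length(object@pairs), nrow(object@incomplete)))
  if (length(object@issues))
    cat(sprintf("  %d file issue(s); see seriesIssues()\n",
                length(object@issues)))
})

setMethod("show", "ResponseModel", function(object) {
  cat(sprintf(paste0("ResponseModel: baseline %.1f deg, A %.1f deg, ",
                     "t50 %g min, k %g/min\n"),
              object@baselineDeg, object@amplitudeDeg, object@halftimeMin,
              object@riseRatePerMin))
  cat(sprintf("  oscillation %.1f deg / %g min; decay %s; sd plant %.2f, frame %.2f\n",
              object@oscAmpDeg, object@oscPeriodMin,
              if (is.na(object@decayStartMin)) "off"
              else sprintf("from %g min, tau %g min", object@decayStartMin,
                           object@decayTauMin),
              object@plantSdDeg, object@frameSdDeg))
})

setMethod("show", "SceneParams", function(object) {
  cat(sprintf(paste0("SceneParams: L = %g mm, theta = %g deg, e = %g, ",
                     "noise sd %g\n"),
              object@leafLengthMm, object@elevationDeg,
              object@eccentricity, object@noiseSd))
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth: r = %.3f mm, h = %.3f mm, LEI = %.3f deg\n",
              object@rTrueMm, object@hTrueMm, object@leiTrueDeg))
})
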