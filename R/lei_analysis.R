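#' Pixel-to-millimetre calibration from a length standard
#'
#' Each camera photographs a ruler or other length standard once; the
#' conversion factor is simply the known physical length divided by its
#' apparent length in pixels.
#'
#' @param pxDistance apparent length in pixels (> 0).
#' @param mmDistance physical length in mm (> 0).
#' @return mm per pixel.
#' @examples
#' calibrate(100, 10)  # 0.1 mm/px
#' @export
calibrate <- function(pxDistance, mmDistance) {
  if (!is.finite(pxDistance) || pxDistance <= 0)
    stop("'pxDistance' must be a positive number", call. = FALSE)
  if (!is.finite(mmDistance) || mmDistance <= 0)
    stop("'mmDistance' must be a positive number", call. = FALSE)
  mmDistance / pxDistance
}

#' Rosette radius from the ellipse axes
#'
#' The rosette is rarely perfectly round, so its diameter is taken as the
#' mean of the ellipse major and minor axes; the cylinder radius is half
#' that, i.e. \code{(major + minor) / 4}.
#'
#' @param majorMm,minorMm full axis lengths in mm,
#'   \code{majorMm >= minorMm >= 0}, not both zero.
#' @return radius in mm.
#' @examples
#' radiusFromAxes(24, 16)  # 10
#' @export
radiusFromAxes <- function(majorMm, minorMm) {
  if (!is.finite(majorMm) || !is.finite(minorMm) ||
      minorMm < 0 || majorMm < minorMm)
    stop("axes must satisfy major >= minor >= 0", call. = FALSE)
  if (majorMm == 0 && minorMm == 0)
    stop("degenerate plant: both ellipse axes are zero", call. = FALSE)
  (majorMm + minorMm) / 4
}

#' Leaf elevation index
#'
#' The plant is treated as a cylinder of radius r and height h; the leaf
#' elevation index is the elevation angle of that cylinder,
#' \deqn{LEI = \tan^{-1}(h / r) \cdot 180 / \pi,} in degrees. It is not
#' the angle of any single leaf but a whole-plant proxy for leaf elevation
#' status: hyponastic (raised) leaves make the plant taller and narrower,
#' increasing the index.
#'
#' @param hMm plant height in mm (>= 0).
#' @param rMm rosette radius in mm (> 0).
#' @return LEI in degrees, in [0, 90).
#' @examples
#' computeLEI(5, 5)  # 45
#' @export
computeLEI <- function(hMm, rMm) {
  if (!all(is.finite(rMm)) || any(rMm <= 0))
    stop("'rMm' must be strictly positive", call. = FALSE)
  if (!all(is.finite(hMm)) || any(hMm < 0))
    stop("'hMm' must be non-negative", call. = FALSE)
  atan(hMm / rMm) * 180 / pi
}

.emptyRecords <- function() {
  df <- as.data.frame(setNames(
    rep(list(numeric(0)), length(.measurementCols)), .measurementCols),
    stringsAsFactors = FALSE)
  df$plant_id <- character(0)
  df
}

#' Measure every complete frame pair of a series
#'
#' For each (plant, timepoint) with both views present: segment both
#' frames, fit the equal-moment ellipse on the top view, measure height
#' above the soil line on the side view, convert with the view-specific
#' calibration and compute the LEI. A failure on one pair (empty
#' segmentation, unreadable file, degenerate geometry) is logged as a skip
#' and the batch continues; nothing is fatal mid-batch.
#'
#' @param series a \linkS4class{SeriesIndex}.
#' @param params a \linkS4class{SegmentationParams}, or a list
#'   \code{list(top =, side =)} with per-view parameters.
#' @param linePosition soil reference row for the side view.
#' @param cal a \linkS4class{Calibration}.
#' @param clipBelowLine passed to \code{\link{measureHeight}}.
#' @param logFun function receiving one progress line per processed pair
#'   (default \code{message}); pass \code{NULL} to silence.
#' @return data.frame with columns \code{plant_id, timestamp_min,
#'   major_px, minor_px, height_px, mm_per_px_top, mm_per_px_side, h_mm,
#'   r_mm, lei_deg}, one row per successfully measured pair, sorted by
#'   plant then time. Skipped pairs are recorded in the \code{"skips"}
#'   attribute (data.frame plant_id, timestamp_min, reason).
#' @export
buildRecords <- function(series, params = SegmentationParams(),
                         linePosition, cal, clipBelowLine = TRUE,
                         logFun = message) {
  stopifnot(is(series, "SeriesIndex"), is(cal, "Calibration"))
  if (is(params, "SegmentationParams"))
    params <- list(top = params, side = params)
  stopifnot(is(params$top, "SegmentationParams"),
            is(params$side, "SegmentationParams"))
  if (is.null(logFun)) logFun <- function(...) invisible(NULL)

  pairs <- series@pairs
  if (length(pairs) == 0L) {
    warning("series contains no complete frame pairs; nothing to measure",
            call. = FALSE)
    out <- .emptyRecords()
    attr(out, "skips") <- data.frame(plant_id = character(0),
                                     timestamp_min = numeric(0),
                                     reason = character(0),
                                     stringsAsFactors = FALSE)
    return(out)
  }

  rows <- vector("list", length(pairs))
  skips <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    pid <- p$top@plantId; tmin <- p$top@timestampMin
    res <- tryCatch({
      topMask <- segmentPlant(loadFrame(p$top), params$top)
      if ("empty" %in% topMask@flags)
        stop("empty top-view segmentation", call. = FALSE)
      sideMask <- segmentPlant(loadFrame(p$side), params$side)
      if ("empty" %in% sideMask@flags)
        stop("empty side-view segmentation", call. = FALSE)
      fit <- fitEllipse(topMask)
      hm <- measureHeight(sideMask, linePosition,
                          clipBelowLine = clipBelowLine)
      majorMm <- fit@majorAxisPx * cal@mmPerPxTop
      minorMm <- fit@minorAxisPx * cal@mmPerPxTop
      rMm <- radiusFromAxes(majorMm, minorMm)
      hMm <- hm@heightPx * cal@mmPerPxSide
      data.frame(plant_id = pid, timestamp_min = tmin,
                 major_px = fit@majorAxisPx, minor_px = fit@minorAxisPx,
                 height_px = hm@heightPx,
                 mm_per_px_top = cal@mmPerPxTop,
                 mm_per_px_side = cal@mmPerPxSide,
                 h_mm = hMm, r_mm = rMm,
                 lei_deg = computeLEI(hMm, rMm),
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skips[[length(skips) + 1L]] <- data.frame(
        plant_id = pid, timestamp_min = tmin, reason = res,
        stringsAsFactors = FALSE)
      logFun(sprintf("SKIP plant %s t=%g min: %s", pid, tmin, res))
    } else {
      rows[[i]] <- res
      logFun(sprintf("OK   plant %s t=%g min: LEI %.2f deg", pid, tmin,
                     res$lei_deg))
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- .emptyRecords()
  out <- out[order(out$plant_id, out$timestamp_min), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skips") <- if (length(skips)) do.call(rbind, skips)
    else data.frame(plant_id = character(0), timestamp_min = numeric(0),
                    reason = character(0), stringsAsFactors = FALSE)
  out
}

#' Aggregate per-plant records into a normalized group trajectory
#'
#' At each timepoint the group mean LEI and its standard error (sample sd
#' over sqrt(n), n = plants contributing at that timepoint) are computed,
#' then the mean trajectory is shifted so that its value at the treatment
#' onset is exactly zero — the reported quantity is the change in leaf
#' elevation, \eqn{\Delta LEI}, relative to treatment begin. With
#' \code{normalize = "plant"} each plant is instead shifted by its own
#' onset value before averaging.
#'
#' A timepoint contributed by a single plant reports SEM 0 and is listed
#' in the \code{"flags"} attribute. Unequal plant counts across timepoints
#' (dropped frames) are handled by using whatever plants are present; n is
#' reported per timepoint.
#'
#' @param records measurement data.frame (needs \code{plant_id,
#'   timestamp_min, lei_deg}).
#' @param label group label (genotype x treatment), copied into the output.
#' @param onsetMin treatment onset in minutes; a record must exist there.
#' @param normalize \code{"group"} (default) or \code{"plant"}.
#' @return data.frame \code{label, timestamp_min, mean_dlei_deg, sem_deg,
#'   n}, sorted by time, with attribute \code{"flags"}.
#' @examples
#' rec <- data.frame(plant_id = rep(c("a", "b", "c"), 2),
#'                   timestamp_min = rep(c(0, 30), each = 3),
#'                   lei_deg = c(1, 2, 3, 2, 3, 4))
#' aggregateGroup(rec, "wt_low", onsetMin = 0)
#' @export
aggregateGroup <- function(records, label, onsetMin,
                           normalize = c("group", "plant")) {
  normalize <- match.arg(normalize)
  stopifnot(is.data.frame(records),
            all(c("plant_id", "timestamp_min", "lei_deg") %in%
                  names(records)))
  if (!any(records$timestamp_min == onsetMin))
    stop("no record at the onset timepoint (", onsetMin,
         " min); normalization undefined", call. = FALSE)

  lei <- records$lei_deg
  if (normalize == "plant") {
    onset <- records[records$timestamp_min == onsetMin, ]
    ref <- setNames(onset$lei_deg, onset$plant_id)
    keep <- records$plant_id %in% names(ref)
    records <- records[keep, ]; lei <- lei[keep]
    lei <- lei - ref[records$plant_id]
  }

  tps <- sort(unique(records$timestamp_min))
  mean_lei <- sem <- nvec <- numeric(length(tps))
  flags <- character(0)
  for (i in seq_along(tps)) {
    v <- lei[records$timestamp_min == tps[i]]
    nvec[i] <- length(v)
    mean_lei[i] <- mean(v)
    if (nvec[i] > 1L) {
      sem[i] <- stats::sd(v) / sqrt(nvec[i])
    } else {
      sem[i] <- 0
      flags <- c(flags, sprintf(
        "t=%g min: single plant, SEM reported as 0", tps[i]))
    }
  }
  ref <- mean_lei[tps == onsetMin]
  out <- data.frame(label = label, timestamp_min = tps,
                    mean_dlei_deg = mean_lei - ref, sem_deg = sem,
                    n = as.integer(nvec), stringsAsFactors = FALSE)
  # exactness at the onset, immune to fp cancellation
  out$mean_dlei_deg[out$timestamp_min == onsetMin] <- 0
  attr(out, "flags") <- flags
  out
}

#' Write group trajectories
#'
#' @param groups data.frame from \code{\link{aggregateGroup}} (or several
#'   rbound together).
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeGroupCourses <- function(groups, path) {
  cols <- c("label", "timestamp_min", "mean_dlei_deg", "sem_deg", "n")
  stopifnot(all(cols %in% names(groups)))
  utils::write.csv(groups[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
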