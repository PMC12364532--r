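#' Excess-green vegetation index
#'
#' Computes ExG = 2G - R - B per pixel on channels scaled to [0, 1], the
#' standard index for separating green plant material from a dark soil
#' background. Output range is [-2, 2]: a pure green pixel scores 2, any
#' gray pixel 0, pure red or blue -1.
#'
#' @param frame a \linkS4class{Frame}, or an H x W x 3 array in [0, 1].
#' @return H x W numeric matrix of index values.
#' @examples
#' f <- Frame(array(c(0, 1, 0), dim = c(1, 1, 3)))
#' excessGreen(f)  # 2
#' @export
excessGreen <- function(frame) {
  px <- if (is(frame, "Frame")) frame@pixels else frame
  stopifnot(length(dim(px)) == 3L, dim(px)[3] == 3L)
  out <- 2 * px[, , 2] - px[, , 1] - px[, , 3]
  if (!is.matrix(out)) out <- matrix(out, dim(px)[1], dim(px)[2])
  out
}

#' Threshold a vegetation-index grid
#'
#' The index is clipped at \code{maxValue} and pixels strictly above
#' \code{threshold} become foreground. Clipping mirrors the ceiling
#' parameter of common phenotyping threshold steps; because
#' \code{threshold < maxValue} is enforced, clipping never erases true
#' foreground, it only caps extreme values.
#'
#' @param index H x W numeric matrix (e.g. from \code{\link{excessGreen}}).
#' @param params a \linkS4class{SegmentationParams}.
#' @param meta optional \linkS4class{FrameMeta} carried into the mask.
#' @return A \linkS4class{BinaryMask}.
#' @export
thresholdMask <- function(index, params = SegmentationParams(),
                          meta = NULL) {
  stopifnot(is.matrix(index))
  m <- pmin(index, params@maxValue) > params@threshold
  BinaryMask(m, meta = meta)
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so
# labels that touch diagonally are merged with a small union-find pass.
.label8 <- function(m) {
  lab <- EBImage::bwlabel(m * 1)
  lab <- matrix(as.integer(round(lab)), nrow(m), ncol(m))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),
                 cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W])))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  pairs <- unique(pairs)
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Clean a binary mask
#'
#' Applies, in order: the region of interest (pixels outside are set to
#' background), hole filling within the remaining foreground, and removal
#' of 8-connected components smaller than \code{params@size} pixels. If
#' several components survive the size filter they are all kept — in the
#' side view a rosette may legitimately fragment across leaves — and this
#' behaviour can be changed with \code{keepLargestOnly}.
#'
#' The operation is idempotent: cleaning an already-clean mask changes
#' nothing.
#'
#' @param mask a \linkS4class{BinaryMask} or logical matrix.
#' @param params a \linkS4class{SegmentationParams}.
#' @param keepLargestOnly if \code{TRUE}, keep only the largest surviving
#'   component (default \code{FALSE}).
#' @return A \linkS4class{BinaryMask}.
#' @export
cleanMask <- function(mask, params = SegmentationParams(),
                      keepLargestOnly = FALSE) {
  meta <- NULL; flags <- character(0)
  if (is(mask, "BinaryMask")) {
    meta <- mask@meta; flags <- mask@flags; m <- mask@mask
  } else m <- mask
  stopifnot(is.matrix(m))
  if (length(params@roi) == 4L) {
    r0 <- params@roi[1]; c0 <- params@roi[2]
    r1 <- r0 + params@roi[3] - 1L; c1 <- c0 + params@roi[4] - 1L
    if (r0 < 1L || c0 < 1L || r1 > nrow(m) || c1 > ncol(m))
      stop("roi [", paste(params@roi, collapse = ", "),
           "] exceeds frame bounds ", nrow(m), " x ", ncol(m),
           call. = FALSE)
    keep <- matrix(FALSE, nrow(m), ncol(m))
    keep[r0:r1, c0:c1] <- TRUE
    m <- m & keep
  }
  if (any(m)) {
    m <- EBImage::fillHull(m * 1) > 0.5
    if (params@size > 0L) {
      lab <- .label8(m)
      sizes <- tabulate(lab[lab > 0L])
      keepIds <- which(sizes >= params@size)
      if (keepLargestOnly && length(keepIds) > 1L)
        keepIds <- keepIds[which.max(sizes[keepIds])]
      m <- matrix(lab %in% keepIds & lab > 0L, nrow(m), ncol(m))
    }
  }
  BinaryMask(m, meta = meta, flags = flags)
}

#' Segment the plant in a frame
#'
#' The full extraction chain: vegetation index, threshold, then mask
#' cleaning. An empty result (no plant found) is flagged on the returned
#' mask rather than raised as an error, so a batch caller can log and skip
#' the time point.
#'
#' @param frame a \linkS4class{Frame}.
#' @param params a \linkS4class{SegmentationParams}, tuned once per series.
#' @param indexFun vegetation-index function mapping a frame to an H x W
#'   matrix; defaults to \code{\link{excessGreen}}.
#' @param keepLargestOnly passed to \code{\link{cleanMask}}.
#' @return A \linkS4class{BinaryMask}; flag \code{"empty"} marks a frame
#'   with no surviving foreground.
#' @examples
#' sc <- renderScene(SceneParams(elevationDeg = 40))
#' m <- segmentPlant(sc$top, SegmentationParams())
#' maskArea(m)
#' @export
segmentPlant <- function(frame, params = SegmentationParams(),
                         indexFun = excessGreen, keepLargestOnly = FALSE) {
  idx <- indexFun(frame)
  m <- thresholdMask(idx, params, meta = frame@meta)
  m <- cleanMask(m, params, keepLargestOnly = keepLargestOnly)
  if (!any(m@mask)) m@flags <- union(m@flags, "empty")
  m
}

#' Dump a mask as an audit PNG
#'
#' Writes the mask as an 8-bit grayscale PNG (foreground 255, background
#' 0) so segmentation quality can be eyeballed frame by frame.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param path output PNG path.
#' @return The path, invisibly.
#' @export
writeMaskPng <- function(mask, path) {
  png::writePNG(mask@mask * 1, path)
  invisible(path)
}
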