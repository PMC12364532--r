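#' Central moments of a binary mask
#'
#' Treats each foreground pixel as a unit point mass at its integer
#' (row, col) coordinate and returns the pixel count, the centroid and the
#' second central moments normalized by the count. These are the exact
#' sufficient statistics for the equal-moment ellipse; no contour is ever
#' extracted. \code{mu20} is the row-coordinate variance, \code{mu02} the
#' column-coordinate variance, \code{mu11} the covariance.
#'
#' @param mask a \linkS4class{BinaryMask} or logical matrix; must contain
#'   at least one foreground pixel.
#' @return A \linkS4class{MaskMoments}.
#' @examples
#' m <- matrix(FALSE, 10, 10); m[5, 7] <- TRUE
#' maskMoments(m)
#' @export
setGeneric("maskMoments", function(mask) standardGeneric("maskMoments"))

#' @rdname maskMoments
#' @export
setMethod("maskMoments", "BinaryMask", function(mask)
  maskMoments(mask@mask))

#' @rdname maskMoments
#' @export
setMethod("maskMoments", "matrix", function(mask) {
  coords <- which(mask, arr.ind = TRUE)
  n <- nrow(coords)
  if (n == 0L)
    stop("cannot measure an empty mask", call. = FALSE)
  r <- coords[, 1]; c <- coords[, 2]
  rbar <- mean(r); cbar <- mean(c)
  dr <- r - rbar; dc <- c - cbar
  new("MaskMoments", n = n, centroid = c(rbar, cbar),
      mu20 = mean(dr * dr), mu02 = mean(dc * dc), mu11 = mean(dr * dc))
})

#' Fit the equal-moment ellipse of a rosette silhouette
#'
#' Returns the ellipse whose second-order moments match those of the mask:
#' with \eqn{\lambda_1 \ge \lambda_2} the eigenvalues of the coordinate
#' covariance matrix, the full major and minor axis lengths are
#' \eqn{4\sqrt{\lambda_1}} and \eqn{4\sqrt{\lambda_2}}. For a filled disc
#' of radius R, \eqn{\lambda = R^2/4}, so the fitted axes equal the
#' diameter. The orientation is the angle of the major axis against the
#' column axis (counter-clockwise, row axis pointing up), in
#' (-pi/2, pi/2].
#'
#' A mask of collinear pixels gives a zero minor axis and is flagged
#' degenerate rather than rejected: the major axis may still carry a
#' usable diameter.
#'
#' @param mask a \linkS4class{BinaryMask} or logical matrix, non-empty.
#' @return An \linkS4class{EllipseFit}.
#' @examples
#' m <- matrix(FALSE, 101, 101)
#' cr <- 51; cc <- 51
#' for (r in 1:101) for (cl in 1:101)
#'   m[r, cl] <- (r - cr)^2 + (cl - cc)^2 <= 40^2
#' fitEllipse(m)  # major ~ minor ~ 80 px
#' @export
setGeneric("fitEllipse", function(mask) standardGeneric("fitEllipse"))

#' @rdname fitEllipse
#' @export
setMethod("fitEllipse", "BinaryMask", function(mask) fitEllipse(mask@mask))

#' @rdname fitEllipse
#' @export
setMethod("fitEllipse", "matrix", function(mask) {
  mm <- maskMoments(mask)
  C <- matrix(c(mm@mu20, mm@mu11, mm@mu11, mm@mu02), 2L, 2L)
  e <- eigen(C, symmetric = TRUE)
  l1 <- max(e$values[1], 0); l2 <- max(e$values[2], 0)
  # eigenvector of the dominant axis, in (row, col) coordinates; express
  # the angle with the row axis pointing up so it matches the usual
  # counter-clockwise convention
  v <- e$vectors[, 1]
  ang <- atan2(-v[1], v[2])
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  degenerate <- l2 <= 1e-12 * max(1, l1)
  new("EllipseFit", centroid = mm@centroid,
      majorAxisPx = 4 * sqrt(l1), minorAxisPx = 4 * sqrt(l2),
      orientationRad = ang, degenerate = degenerate)
})

#' Measure plant height above the soil line
#'
#' On the side view, height is the row distance between the highest
#' foreground pixel and the soil reference row (\code{linePosition}); rows
#' increase downward. With \code{clipBelowLine = TRUE} (the default),
#' pixels at or below the soil line — pot, soil, reflections — are ignored
#' entirely; a mask living wholly at or below the line then yields height
#' 0 with a flag rather than an error, so batch processing continues.
#'
#' When several components survive segmentation the highest pixel over all
#' of them wins: individual raised leaves count.
#'
#' @param mask a \linkS4class{BinaryMask} or logical matrix, non-empty.
#' @param linePosition soil reference row (1-based, within the image).
#' @param clipBelowLine ignore pixels at or below the line (default
#'   \code{TRUE}).
#' @return A \linkS4class{HeightMeasurement}.
#' @examples
#' m <- matrix(FALSE, 200, 100); m[20:100, 40:60] <- TRUE
#' heightPx(measureHeight(m, linePosition = 100))  # 80
#' @export
setGeneric("measureHeight", function(mask, linePosition,
                                     clipBelowLine = TRUE)
  standardGeneric("measureHeight"))

#' @rdname measureHeight
#' @export
setMethod("measureHeight", "BinaryMask",
  function(mask, linePosition, clipBelowLine = TRUE)
    measureHeight(mask@mask, linePosition, clipBelowLine))

#' @rdname measureHeight
#' @export
setMethod("measureHeight", "matrix",
  function(mask, linePosition, clipBelowLine = TRUE) {
    stopifnot(length(linePosition) == 1L, linePosition >= 1,
              linePosition <= nrow(mask))
    rows <- which(rowSums(mask) > 0L)
    if (length(rows) == 0L)
      stop("cannot measure an empty mask", call. = FALSE)
    if (clipBelowLine) rows <- rows[rows < linePosition]
    if (length(rows) == 0L)
      return(new("HeightMeasurement", heightPx = 0, topRow = NA_real_,
                 linePosition = as.numeric(linePosition), flagged = TRUE))
    topRow <- min(rows)
    new("HeightMeasurement",
        heightPx = max(0, linePosition - topRow),
        topRow = as.numeric(topRow),
        linePosition = as.numeric(linePosition),
        flagged = FALSE)
  })
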