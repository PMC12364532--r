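#' Parse a time-lapse frame filename
#'
#' The capture convention encodes identity and time in the filename:
#' \code{<plantID>_<view>_<minutes>.png} (or \code{.jpg}/\code{.jpeg}),
#' e.g. \code{p07_top_0600.png} for plant p07 photographed from above at
#' 600 minutes. The view token is matched case-insensitively; the plant id
#' may itself contain underscores. A different convention can be supplied
#' as a regular expression with three capture groups (id, view, minutes).
#'
#' @param name file name (a path is reduced to its basename).
#' @param pattern optional regular expression overriding the default
#'   convention; must contain exactly three capture groups.
#' @return A \linkS4class{FrameMeta} with \code{path = name}.
#' @examples
#' parseFrameFilename("p07_top_0600.png")
#' @export
parseFrameFilename <- function(name, pattern = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(pattern))
    pattern <- "^(.+)_([A-Za-z]+)_([0-9]+)\\.(?:png|jpe?g)$"
  base <- basename(name)
  m <- regmatches(base, regexec(pattern, base, ignore.case = TRUE))[[1]]
  if (length(m) < 4L)
    stop("cannot parse frame filename '", base,
         "': expected <plantID>_<view>_<minutes>.<png|jpg>", call. = FALSE)
  view <- tolower(m[3])
  if (!view %in% c("top", "side"))
    stop("unknown view token '", m[3], "' in '", base,
         "': expected 'top' or 'side'", call. = FALSE)
  FrameMeta(plantId = m[2], view = view,
            timestampMin = as.numeric(m[4]), path = name)
}

#' Index a directory of paired time-lapse images
#'
#' Scans a directory for PNG/JPEG frames, parses their filenames, snaps
#' timestamps onto the sampling grid and groups frames into
#' (plant, timestamp) pairs. A pair is complete when both the top and the
#' side view are present; anything else (missing views, unparseable names,
#' timestamps off the grid) is reported, never silently dropped.
#'
#' Timestamps within 10\% of the sampling interval of a grid point are
#' snapped to it, absorbing capture jitter; frames further off the grid are
#' listed under \code{seriesIssues()} and excluded.
#'
#' @param directory directory containing the images.
#' @param intervalMin sampling interval in minutes (default 30, the usual
#'   capture cadence).
#' @param pattern optional filename pattern, see
#'   \code{\link{parseFrameFilename}}.
#' @return A \linkS4class{SeriesIndex}.
#' @export
indexSeries <- function(directory, intervalMin = 30, pattern = NULL) {
  stopifnot(length(intervalMin) == 1L, intervalMin > 0)
  if (!dir.exists(directory))
    stop("directory not readable: ", directory, call. = FALSE)
  files <- list.files(directory, pattern = "\\.(png|jpe?g)$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- files[!grepl("mask", basename(files), ignore.case = TRUE)]
  if (length(files) == 0L)
    stop("no PNG/JPEG images found in ", directory, call. = FALSE)

  issues <- character(0)
  metas <- list()
  for (f in files) {
    meta <- tryCatch(parseFrameFilename(f, pattern = pattern),
                     error = function(e) conditionMessage(e))
    if (is.character(meta)) {
      issues <- c(issues, meta)
      next
    }
    # snap onto the sampling grid
    t0 <- meta@timestampMin
    grid <- round(t0 / intervalMin) * intervalMin
    if (abs(t0 - grid) <= 0.1 * intervalMin) {
      meta@timestampMin <- grid
      metas[[length(metas) + 1L]] <- meta
    } else {
      issues <- c(issues, sprintf(
        "timestamp %g of '%s' is off the %g-min grid; frame excluded",
        t0, basename(f), intervalMin))
    }
  }
  if (length(metas) == 0L)
    stop("no usable frames in ", directory, ": ",
         paste(issues, collapse = "; "), call. = FALSE)

  key3 <- vapply(metas, function(m)
    paste(m@plantId, m@timestampMin, m@view, sep = "@"), character(1))
  dup <- duplicated(key3)
  if (any(dup)) {
    k <- key3[dup][1]
    paths <- vapply(metas[key3 == k], function(m) m@path, character(1))
    stop("duplicate frame for (plant, view, timestamp) ", k, ": ",
         paste(paths, collapse = " and "), call. = FALSE)
  }

  key2 <- vapply(metas, function(m)
    paste(m@plantId, m@timestampMin, sep = "@"), character(1))
  pairs <- list()
  incomplete <- data.frame(plant_id = character(0),
                           timestamp_min = numeric(0),
                           missing_view = character(0),
                           stringsAsFactors = FALSE)
  for (k in unique(key2)) {
    grp <- metas[key2 == k]
    views <- vapply(grp, function(m) m@view, character(1))
    if (all(c("top", "side") %in% views)) {
      pairs[[k]] <- list(top = grp[[which(views == "top")]],
                         side = grp[[which(views == "side")]])
    } else {
      miss <- setdiff(c("top", "side"), views)
      incomplete <- rbind(incomplete, data.frame(
        plant_id = grp[[1]]@plantId,
        timestamp_min = grp[[1]]@timestampMin,
        missing_view = paste(miss, collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  plants <- sort(unique(vapply(metas, function(m) m@plantId, character(1))))
  tps <- sort(unique(vapply(metas, function(m) m@timestampMin, numeric(1))))
  # deterministic ordering: plant, then time
  if (length(pairs)) {
    ord <- order(vapply(pairs, function(p) p$top@plantId, character(1)),
                 vapply(pairs, function(p) p$top@timestampMin, numeric(1)))
    pairs <- pairs[ord]
  }
  new("SeriesIndex", plants = plants, timepoints = tps, pairs = pairs,
      incomplete = incomplete, issues = issues)
}

#' Load a frame from disk
#'
#' Reads a PNG or JPEG image into a \linkS4class{Frame}. Grayscale sources
#' are promoted to RGB by channel replication; an alpha channel, if
#' present, is dropped.
#'
#' @param meta a \linkS4class{FrameMeta} whose \code{path} points at a
#'   decodable image, or a file path (parsed with
#'   \code{\link{parseFrameFilename}}).
#' @return A \linkS4class{Frame} with channel values in [0, 1].
#' @export
loadFrame <- function(meta) {
  if (is.character(meta)) meta <- parseFrameFilename(meta)
  path <- meta@path
  if (is.na(path) || !file.exists(path))
    stop("frame file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch({
    if (ext == "png") {
      png::readPNG(path)
    } else {
      img <- EBImage::readImage(path)
      a <- EBImage::imageData(img)
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    }
  }, error = function(e)
    stop("cannot decode image '", path, "': ", conditionMessage(e),
         call. = FALSE))
  if (is.matrix(px))
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L)
    px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] == 1L)
    px <- array(rep(px, 3L), dim = c(dim(px)[1:2], 3L))
  px[px < 0] <- 0; px[px > 1] <- 1
  Frame(px, meta = meta)
}

.measurementCols <- c("plant_id", "timestamp_min", "major_px", "minor_px",
                      "height_px", "mm_per_px_top", "mm_per_px_side",
                      "h_mm", "r_mm", "lei_deg")

#' Write per-plant LEI measurements
#'
#' Writes the record table produced by \code{\link{buildRecords}} as CSV
#' (RFC 4180, header row, '.' decimal) or as a JSON list of flat records.
#' Both formats hold the same columns and round-trip losslessly through
#' \code{\link{readMeasurements}}.
#'
#' @param records data.frame of LEI records (one row per plant and
#'   timepoint); must be non-empty.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"json"}; defaults to the file
#'   extension.
#' @return The path, invisibly.
#' @export
writeMeasurements <- function(records, path,
                              format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("no records to write", call. = FALSE)
  missing <- setdiff(.measurementCols, names(records))
  if (length(missing))
    stop("records lack required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  records <- records[, .measurementCols]
  ok <- tryCatch({
    if (format == "csv") {
      utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
    } else {
      jsonlite::write_json(records, path, dataframe = "rows",
                           digits = NA, auto_unbox = TRUE)
    }
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok))
    stop("cannot write measurements to '", path, "': ", ok, call. = FALSE)
  invisible(path)
}

#' Read back a measurement table
#'
#' @param path a CSV or JSON file written by \code{\link{writeMeasurements}}.
#' @return data.frame with the standard measurement columns.
#' @export
readMeasurements <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  df$plant_id <- as.character(df$plant_id)
  for (col in setdiff(.measurementCols, "plant_id"))
    df[[col]] <- as.numeric(df[[col]])
  df[, .measurementCols]
}
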