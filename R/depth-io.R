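#' Read a depth video stored as one frame per CSV row
#'
#' The camera stream dialect: a headerless CSV in which each row holds one
#' frame as 23,232 comma-separated distance values in metres, flattened
#' row-major from the 132 x 176 raster (all 176 columns of image row 1,
#' then row 2, ...). Values are used as-is; zero-distance dropout pixels are
#' kept so that no information is lost at read time.
#'
#' @param path Path to the CSV file.
#' @param session Session tag attached to every frame (default `""`).
#' @return List of [DepthFrame-class]; row `k` of the file (1-based) becomes
#'   the frame with index `k - 1`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeDepthCSV(list(depthFrame(matrix(3, 132, 176))), f)
#' frames <- readDepthCSV(f)
#' length(frames)
readDepthCSV <- function(path, session = "") {
  if (!file.exists(path))
    stop("depth CSV not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  nvals <- .FRAME_ROWS * .FRAME_COLS
  frames <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[[k]], ",", fixed = TRUE)[[1L]]
    if (length(fields) != nvals)
      stop(sprintf("malformed frame: row %d has %d fields, expected %d",
                   k, length(fields), nvals))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1L]
      stop(sprintf("parse error at row %d, field %d: '%s' is not numeric",
                   k, bad, fields[bad]))
    }
    frames[[k]] <- depthFrame(
      matrix(vals, .FRAME_ROWS, .FRAME_COLS, byrow = TRUE),
      index = k - 1L, session = session)
  }
  frames
}

#' Write depth frames in the one-frame-per-row CSV dialect
#'
#' Inverse of [readDepthCSV()]: each frame is flattened row-major into a
#' 23,232-field CSV row, in list order. An empty collection yields an empty
#' (headerless) file.
#'
#' @param frames List of [DepthFrame-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeDepthCSV <- function(frames, path) {
  if (length(frames) == 0L) {
    ok <- file.create(path)
    if (!ok) stop("cannot write depth CSV: ", path)
    return(invisible(path))
  }
  flat <- t(vapply(frames, function(fr) {
    stopifnot(is(fr, "DepthFrame"))
    as.vector(t(fr@values))
  }, numeric(.FRAME_ROWS * .FRAME_COLS)))
  data.table::fwrite(data.table::as.data.table(flat), path,
                     col.names = FALSE)
  invisible(path)
}

#' Read per-frame ground truth from JSON lines
#'
#' One JSON record per line, one record per frame:
#' `{"frame": k, "objects": [{"box": [x_min, y_min, x_max, y_max],`
#' `"track_id": i, "label": "lame"|"sound"|"human", "visibility": v}, ...]}`.
#' Boxes are 0-based half-open pixel coordinates (x = column, y = row);
#' `visibility` is the visible fraction of the object's full footprint and
#' defaults to 1 when absent.
#'
#' @param path Path to a JSON-lines ground-truth file.
#' @return List of records, each a list with `frame` (integer) and
#'   `objects` (list of lists with `box`, `track_id`, `label`,
#'   `visibility`), ordered by frame index.
#' @export
readGroundTruth <- function(path) {
  if (!file.exists(path))
    stop("ground-truth file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, function(ln) {
    r <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    r$frame <- as.integer(r$frame)
    r$objects <- lapply(r$objects, function(o) {
      list(box = as.numeric(unlist(o$box)),
           track_id = as.integer(o$track_id),
           label = as.character(o$label),
           visibility = if (is.null(o$visibility)) 1
                        else as.numeric(o$visibility))
    })
    r
  })
  recs[order(vapply(recs, `[[`, integer(1), "frame"))]
}

#' Write per-frame ground truth as JSON lines
#'
#' @param truth List of records as returned by [readGroundTruth()] or
#'   [renderScene()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  lines <- vapply(truth, function(r) {
    jsonlite::toJSON(list(frame = r$frame, objects = r$objects),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' SessionManifest: bookkeeping for one recording session
#'
#' Frame indices of a session in order, the herd size, and (optionally) the
#' session's ground-truth records.
#'
#' @slot frames Strictly increasing integer vector of frame indices.
#' @slot cowCount Integer herd size for the session.
#' @slot groundTruth List of ground-truth records (possibly empty).
#' @export
setClass("SessionManifest",
  representation(frames = "integer", cowCount = "integer",
                 groundTruth = "list"))

setValidity("SessionManifest", function(object) {
  if (length(object@frames) > 1L && any(diff(object@frames) <= 0L))
    return("frame indices must be strictly increasing")
  if (length(object@cowCount) != 1L || object@cowCount < 0L)
    return("cowCount must be a single non-negative integer")
  TRUE
})

#' Construct a SessionManifest
#'
#' @param frames Integer vector of frame indices (strictly increasing).
#' @param cowCount Herd size for the session.
#' @param groundTruth Optional list of ground-truth records.
#' @return A [SessionManifest-class] object.
#' @export
sessionManifest <- function(frames, cowCount = 0L, groundTruth = list()) {
  new("SessionManifest", frames = as.integer(frames),
      cowCount = as.integer(cowCount), groundTruth = groundTruth)
}

setMethod("show", "SessionManifest", function(object) {
  cat(sprintf("SessionManifest  %d frames, %d cows, ground truth: %s\n",
              length(object@frames), object@cowCount,
              if (length(object@groundTruth)) "yes" else "no"))
})
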