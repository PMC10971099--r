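#' Keep only full-width observations of a track
#'
#' Feature extraction uses only frames in which the cow's bounding box
#' spans all 176 columns (`x_min = 0`, `x_max = 176`), i.e. the animal
#' crosses the whole field of view, so the backbone profile covers the
#' full body. Order is preserved; the result may be empty.
#'
#' @param track A [Track-class].
#' @return A [Track-class] with the non-full-width observations removed.
#' @export
selectFullWidthFrames <- function(track) {
  stopifnot(is(track, "Track"))
  keep <- vapply(track@regions, function(r)
    r@box[1] == 0 && r@box[3] == .FRAME_COLS, logical(1))
  new("Track", trackId = track@trackId,
      frameIndices = track@frameIndices[keep],
      regions = track@regions[keep])
}

#' Depth-to-height transform of a masked depth grid
#'
#' Re-expresses masked camera-to-surface distances as heights above the
#' reference floor: in-mask pixels become `distance - depth`, clamped below
#' at 0 (heights are physically non-negative; clamping keeps the
#' column-max robust to sensor noise below the floor). Outside-mask pixels
#' are exactly 0.
#'
#' @param maskedDepth 132 x 176 numeric matrix, e.g. from
#'   [extractDepthRegion()].
#' @param distance Reference distance from camera to floor (m), default
#'   2.8.
#' @param mask Optional logical matrix; defaults to `maskedDepth != 0`.
#' @return 132 x 176 numeric height field (m).
#' @export
heightTransform <- function(maskedDepth, distance = 2.8, mask = NULL) {
  stopifnot(distance > 0)
  if (is.null(mask)) mask <- maskedDepth != 0
  out <- matrix(0, nrow(maskedDepth), ncol(maskedDepth))
  out[mask] <- pmax(distance - maskedDepth[mask], 0)
  out
}

#' Normalised discrete Gaussian kernel
#'
#' The isotropic 2-D Gaussian `exp(-(x^2 + y^2) / (2 sigma^2))` sampled on
#' an integer grid of radius `radius` and normalised to sum to 1.
#'
#' @param sigma Standard deviation in pixels (> 0).
#' @param radius Kernel radius in pixels; default `ceiling(3 * sigma)`.
#' @return `(2 radius + 1)` square matrix of weights summing to 1.
#' @export
gaussianKernel <- function(sigma, radius = ceiling(3 * sigma)) {
  stopifnot(sigma > 0, radius >= 1)
  x <- -radius:radius
  w <- exp(-x^2 / (2 * sigma^2))
  k <- outer(w, w)
  k / sum(k)
}

## 1-D convolution along the rows of `mat` (i.e. smoothing down each
## column) with reflective borders (edge pixel duplicated).
.convCols <- function(mat, w) {
  r <- (length(w) - 1L) / 2L
  n <- nrow(mat)
  padded <- rbind(mat[r:1, , drop = FALSE], mat,
                  mat[n:(n - r + 1L), , drop = FALSE])
  out <- matrix(0, n, ncol(mat))
  for (k in seq_along(w))
    out <- out + w[k] * padded[(k - 1L) + seq_len(n), , drop = FALSE]
  out
}

#' Gaussian-smooth a height field
#'
#' Convolves the field with the normalised discrete Gaussian kernel of
#' [gaussianKernel()]. The kernel is separable, so smoothing is applied as
#' two 1-D passes; borders are handled reflectively (edge pixel
#' duplicated) and the output has the input's shape. A constant field is
#' left unchanged and no value can exceed the input maximum
#' (convex-combination property).
#'
#' @param field Numeric matrix (a height field).
#' @param sigma Gaussian SD in pixels, default 1.
#' @param radius Kernel radius, default `ceiling(3 * sigma)`.
#' @return Smoothed matrix of the same shape.
#' @export
gaussianSmooth <- function(field, sigma = 1, radius = ceiling(3 * sigma)) {
  stopifnot(sigma > 0, radius >= 1)
  x <- -radius:radius
  w <- exp(-x^2 / (2 * sigma^2))
  w <- w / sum(w)
  t(.convCols(t(.convCols(field, w)), w))
}

#' Backbone height profile: per-column maxima
#'
#' The feature vector of the lameness classifier: for each column, the
#' maximum over the rows of the (smoothed) height field -- the highest
#' dorsal point at that position along the corridor axis. On the standard
#' 132 x 176 field this yields the length-176 feature vector. Background
#' is 0 and animal heights are positive, so taking the maximum over the
#' whole column equals taking it over the animal.
#'
#' @param field Numeric matrix (a height field).
#' @return Numeric vector of length `ncol(field)` (m).
#' @export
#' @examples
#' f <- matrix(0, 132, 176); f[60, 10] <- 1.3
#' backboneProfile(f)[10]
backboneProfile <- function(field) {
  apply(field, 2L, max)
}

#' Extract backbone profiles from a track
#'
#' The full feature pipeline for one tracked cow: keep full-width frames,
#' mask-extract the depth region, transform depth to height above the
#' floor, Gaussian-smooth, and take per-column maxima. Each kept frame
#' yields one length-176 feature vector.
#'
#' @param track A [Track-class].
#' @param frames List of [DepthFrame-class] covering the track's frames.
#' @param distance Reference camera-to-floor distance (m), default 2.8.
#' @param sigma Gaussian SD in pixels, default 1.
#' @param radius Kernel radius, default `ceiling(3 * sigma)`.
#' @return List with `profiles` (matrix, one row per kept frame, 176
#'   columns), `frameIndices`, and `trackId`. When no frame is full-width
#'   the matrix has zero rows and a warning records the empty selection.
#' @export
featurizeTrack <- function(track, frames, distance = 2.8, sigma = 1,
                           radius = ceiling(3 * sigma)) {
  stopifnot(is(track, "Track"), length(track@frameIndices) > 0L)
  sel <- selectFullWidthFrames(track)
  if (length(sel@frameIndices) == 0L) {
    warning("track ", track@trackId, ": no full-width frames to featurise")
    return(list(profiles = matrix(0, 0L, .FRAME_COLS),
                frameIndices = integer(0), trackId = track@trackId))
  }
  lut <- .frameLookup(frames)
  profiles <- t(vapply(seq_along(sel@frameIndices), function(k) {
    fr <- lut[[as.character(sel@frameIndices[k])]]
    if (is.null(fr))
      stop("no depth frame with index ", sel@frameIndices[k])
    masked <- extractDepthRegion(fr, sel@regions[[k]])
    h <- heightTransform(masked, distance, mask = sel@regions[[k]]@mask)
    backboneProfile(gaussianSmooth(h, sigma, radius))
  }, numeric(.FRAME_COLS)))
  list(profiles = profiles, frameIndices = sel@frameIndices,
       trackId = track@trackId)
}

#' Feature table for a set of tracks
#'
#' Runs [featurizeTrack()] on every track and stacks the results into a
#' data frame with columns `track_id`, `frame_index` and `h_000` ...
#' `h_175` (metres). Tracks without full-width frames contribute no rows.
#'
#' @inheritParams featurizeTrack
#' @param tracks List of [Track-class].
#' @return Data frame, one row per featurised frame.
#' @export
featureTable <- function(tracks, frames, distance = 2.8, sigma = 1,
                         radius = ceiling(3 * sigma)) {
  parts <- lapply(tracks, function(tr) {
    ft <- withCallingHandlers(
      featurizeTrack(tr, frames, distance, sigma, radius),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(ft$profiles) == 0L) return(NULL)
    cbind(data.frame(track_id = ft$trackId, frame_index = ft$frameIndices),
          as.data.frame(ft$profiles))
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L) {
    out <- cbind(data.frame(track_id = integer(0), frame_index = integer(0)),
                 as.data.frame(matrix(0, 0, .FRAME_COLS)))
  } else out <- do.call(rbind, parts)
  names(out)[-(1:2)] <- sprintf("h_%03d", seq_len(.FRAME_COLS) - 1L)
  rownames(out) <- NULL
  out
}
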