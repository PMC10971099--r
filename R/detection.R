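#' Label connected components of a binary mask
#'
#' Components are found on the pixel grid with 8-connectivity by default
#' (diagonal neighbours join), using an explicit neighbour-edge graph and
#' `igraph::components()`. Returned masks are ordered largest first.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param minArea Drop components smaller than this many pixels.
#' @return List of logical matrices, one per component, decreasing area.
#' @export
connectedComponents <- function(mask, connectivity = 8, minArea = 0) {
  stopifnot(is.logical(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(list())
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  dirs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8)
    dirs <- c(dirs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (d in dirs) {
    dr <- d[1L]; dc <- d[2L]
    rs <- max(1L, 1L - dr):min(nr, nr - dr)
    cs <- max(1L, 1L - dc):min(nc, nc - dc)
    both <- mask[rs, cs, drop = FALSE] & mask[rs + dr, cs + dc, drop = FALSE]
    w <- which(both, arr.ind = TRUE)
    if (nrow(w) == 0L) next
    a <- (cs[w[, 2L]] - 1L) * nr + rs[w[, 1L]]
    b <- a + dr + dc * nr
    edges <- c(edges, rbind(pos[a], pos[b]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  membership <- igraph::components(g)$membership
  groups <- split(idx, membership)
  groups <- groups[order(-lengths(groups))]
  groups <- groups[lengths(groups) >= minArea]
  lapply(groups, function(px) {
    m <- matrix(FALSE, nr, nc)
    m[px] <- TRUE
    m
  })
}

#' Reference depth-threshold detector
#'
#' A transparent stand-in for a trained instance detector, sufficient for
#' the flat-floor geometry: pixels whose height above the floor
#' (`cameraHeightM - depth`) exceeds `fgDeltaM` are foreground, and
#' 8-connected foreground components of at least `minArea` pixels become
#' instance masks, largest first. Real detector output can be plugged in
#' instead via [masksDetector()] or any function with the same contract
#' (one [DepthFrame-class] in, a list of logical masks out).
#'
#' @param frame A [DepthFrame-class].
#' @param cameraHeightM Camera height above the floor (m), default 3.
#' @param fgDeltaM Minimum height above the floor to count as foreground
#'   (m), default 0.1.
#' @param minArea Minimum component area in pixels, default 50 (suppresses
#'   sensor speckle).
#' @return List of logical 132 x 176 masks; empty when no foreground.
#' @export
referenceDetect <- function(frame, cameraHeightM = 3, fgDeltaM = 0.1,
                            minArea = 50) {
  stopifnot(is(frame, "DepthFrame"), fgDeltaM > 0)
  fg <- (cameraHeightM - frame@values) > fgDeltaM
  connectedComponents(fg, connectivity = 8, minArea = minArea)
}

#' Pluggable detector reading externally produced mask rasters
#'
#' Accepts per-frame instance masks written by an external model as
#' lossless 0/255 PNG files named `<frame_index>_<k>.png` in one directory.
#'
#' @param dir Directory of mask PNGs.
#' @return A detector function: [DepthFrame-class] -> list of logical masks.
#' @export
masksDetector <- function(dir) {
  stopifnot(dir.exists(dir))
  force(dir)
  function(frame) {
    files <- sort(list.files(
      dir, pattern = sprintf("^%d_\\d+\\.png$", frame@index),
      full.names = TRUE))
    lapply(files, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      if (!identical(dim(img), c(.FRAME_ROWS, .FRAME_COLS)))
        stop("mask raster has wrong dimensions: ", f)
      img > 0.5
    })
  }
}

#' Detect instance regions in a sequence of frames
#'
#' Runs a detector over every frame and wraps each returned mask as an
#' [InstanceRegion-class] (kind `"cow"`, i.e. not yet filtered).
#'
#' @param frames List of [DepthFrame-class].
#' @param detector Function mapping a frame to a list of logical masks;
#'   default the reference detector with standard geometry.
#' @return List (one element per frame) of lists of
#'   [InstanceRegion-class].
#' @export
detectFrames <- function(frames, detector = referenceDetect) {
  lapply(frames, function(fr) {
    lapply(detector(fr), function(m) instanceRegion(fr, m, kind = "cow"))
  })
}

#' Pixel-sum noise filter
#'
#' Regions whose masked depth pixel sum strictly exceeds the threshold keep
#' kind `"cow"`; all others (typically human-sized blobs, whose small
#' footprint keeps the sum low) become `"rejected"` and are excluded from
#' tracking. The inequality is strict: a sum exactly at the threshold is
#' rejected. Order is preserved and the filter is idempotent.
#'
#' @param regions List of [InstanceRegion-class].
#' @param threshold Metre-pixel threshold, default 4000. The default
#'   assumes metre-scale depth values; rescale it when using other units.
#' @return The same list with `kind` updated.
#' @export
noiseFilter <- function(regions, threshold = 4000) {
  stopifnot(threshold > 0)
  lapply(regions, function(r) {
    r@kind <- if (r@pixelSum > threshold) "cow" else "rejected"
    r
  })
}

#' Extract the masked depth region of one instance
#'
#' Element-wise multiplication of the binary mask with the frame's depth
#' values: in-mask pixels keep their depth exactly, outside-mask pixels are
#' exactly 0.
#'
#' @param frame A [DepthFrame-class].
#' @param region An [InstanceRegion-class] detected in that frame.
#' @return 132 x 176 numeric matrix of masked depths.
#' @export
extractDepthRegion <- function(frame, region) {
  stopifnot(is(frame, "DepthFrame"), is(region, "InstanceRegion"))
  frame@values * region@mask
}
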