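## Fraction of the dorsal height removed at mid-body by a full arch
## (arch = 1); see dorsalProfile().
.ARCH_DEPTH <- 0.25

#' CowTemplate: parametric body shape for the simulator
#'
#' A simulated animal (or human) is a separable height surface: an
#' along-body dorsal curve (see [dorsalProfile()]) multiplied by an
#' elliptical cross-body factor. The surface's per-column maximum equals
#' the dorsal curve exactly, which makes the backbone feature extractor's
#' oracle analytic.
#'
#' The generator's labelling convention follows the 1.2 m dorsal-height
#' boundary: templates with `peakHeightM < 1.2` are lame (lowered, arched
#' back), templates with `peakHeightM >= 1.2` are sound.
#'
#' @slot lengthPx Body length in columns.
#' @slot widthPx Body width in rows.
#' @slot peakHeightM Maximum dorsal height above the floor (m).
#' @slot arch Arch coefficient in \[0, 1\]: 0 is a straight dorsal line,
#'   larger values depress the mid-body relative to shoulder/hip.
#' @slot speedPxPerFrame Horizontal displacement per frame (columns).
#' @slot kind `"cow"` or `"human"`.
#' @export
setClass("CowTemplate",
  representation(lengthPx = "integer", widthPx = "integer",
                 peakHeightM = "numeric", arch = "numeric",
                 speedPxPerFrame = "numeric", kind = "character"))

setValidity("CowTemplate", function(object) {
  if (object@lengthPx < 3L || object@widthPx < 3L)
    return("body must be at least 3 x 3 pixels")
  if (object@peakHeightM <= 0)
    return("peakHeightM must be positive")
  if (object@arch < 0 || object@arch > 1)
    return("arch must lie in [0, 1]")
  if (object@speedPxPerFrame <= 0)
    return("speedPxPerFrame must be positive")
  if (!object@kind %in% c("cow", "human"))
    return("kind must be 'cow' or 'human'")
  TRUE
})

#' Construct a cow template
#'
#' Defaults give an adult cow that spans the full 176-column frame width
#' when centred, so full-width frames (the only frames used for feature
#' extraction) arise once per traversal.
#'
#' @param peakHeightM Maximum dorsal height (m); `< 1.2` labels the cow
#'   lame, `>= 1.2` sound.
#' @param arch Arch coefficient in \[0, 1\].
#' @param lengthPx,widthPx Body size in pixels.
#' @param speedPxPerFrame Columns travelled per frame.
#' @return A [CowTemplate-class] object.
#' @export
#' @examples
#' lame <- cowTemplate(peakHeightM = 1.05, arch = 0.6)
#' sound <- cowTemplate(peakHeightM = 1.4, arch = 0)
cowTemplate <- function(peakHeightM = 1.4, arch = 0, lengthPx = 176L,
                        widthPx = 56L, speedPxPerFrame = 8) {
  new("CowTemplate", lengthPx = as.integer(lengthPx),
      widthPx = as.integer(widthPx), peakHeightM = peakHeightM,
      arch = arch, speedPxPerFrame = speedPxPerFrame, kind = "cow")
}

#' Construct a human template (noise blob)
#'
#' A person seen from above: a small dome-shaped blob. Its footprint is
#' small enough that, under the default 3 m geometry, the masked pixel sum
#' stays at or below the 4000 metre-pixel noise threshold, so the noise
#' filter can reject it.
#'
#' @param peakHeightM Head height above the floor (m).
#' @param lengthPx,widthPx Footprint size in pixels.
#' @param speedPxPerFrame Columns travelled per frame.
#' @return A [CowTemplate-class] object with `kind = "human"`.
#' @export
humanTemplate <- function(peakHeightM = 1.7, lengthPx = 30L, widthPx = 16L,
                          speedPxPerFrame = 6) {
  new("CowTemplate", lengthPx = as.integer(lengthPx),
      widthPx = as.integer(widthPx), peakHeightM = peakHeightM,
      arch = 0, speedPxPerFrame = speedPxPerFrame, kind = "human")
}

## Unnormalised along-body shape at continuous coordinate u in (0, L):
## an elliptical taper to zero at head and tail, depressed mid-body by the
## arch term.
.dorsalShape <- function(template, u) {
  L <- template@lengthPx
  taper <- sqrt(pmax(0, 1 - (2 * u / L - 1)^2))
  bump <- (1 - cos(2 * pi * u / L)) / 2
  taper * (1 - .ARCH_DEPTH * template@arch * bump)
}

## Normalisation constant: max of the shape over the pixel-centre grid, so
## that the rendered per-column maximum attains peakHeightM exactly.
.dorsalNorm <- function(template) {
  max(.dorsalShape(template, seq_len(template@lengthPx) - 0.5))
}

#' Along-body dorsal height curve of a template
#'
#' The height curve evaluated at pixel-column centres along the body
#' (length `lengthPx`). Its maximum equals `peakHeightM` exactly; with
#' `arch = 0` the curve is the plain elliptical taper, and `arch > 0`
#' depresses the mid-body smoothly relative to shoulder and hip. This is
#' the analytic oracle for the backbone profile extractor: on noise-free
#' renders the per-column maximum height inside the animal's box equals
#' this curve.
#'
#' @param template A [CowTemplate-class].
#' @return Numeric vector of length `lengthPx`, heights in metres.
#' @export
#' @examples
#' max(dorsalProfile(cowTemplate(peakHeightM = 1.1, arch = 1)))  # 1.1
dorsalProfile <- function(template) {
  stopifnot(is(template, "CowTemplate"))
  u <- seq_len(template@lengthPx) - 0.5
  template@peakHeightM * .dorsalShape(template, u) / .dorsalNorm(template)
}

#' SceneConfig: a fully specified synthetic scene
#'
#' Camera geometry, frame count, the animals and humans with their entry
#' frames and lane rows, per-pixel Gaussian sensor noise, and the RNG seed
#' that fixes the rendered sequence bit-for-bit.
#'
#' @slot cameraHeightM Camera height above the flat floor (m).
#' @slot nFrames Number of frames to render.
#' @slot cows List of `list(template, entryFrame, laneRow)` records.
#' @slot humans List of `list(template, entryFrame, laneRow)` records.
#' @slot noiseSdM Per-pixel Gaussian sensor noise SD (m).
#' @slot seed Integer RNG seed.
#' @slot allowOverlap Logical; permit objects to overlap (stress scenes).
#' @export
setClass("SceneConfig",
  representation(cameraHeightM = "numeric", nFrames = "integer",
                 cows = "list", humans = "list", noiseSdM = "numeric",
                 seed = "integer", allowOverlap = "logical"))

setValidity("SceneConfig", function(object) {
  if (object@cameraHeightM <= 0) return("cameraHeightM must be positive")
  if (object@nFrames < 1L) return("nFrames must be at least 1")
  if (object@noiseSdM < 0) return("noiseSdM must be non-negative")
  for (ob in c(object@cows, object@humans)) {
    tpl <- ob$template
    if (!is(tpl, "CowTemplate")) return("each object needs a CowTemplate")
    if (tpl@peakHeightM >= object@cameraHeightM)
      return("every peak height must be below the camera height")
    b <- tpl@widthPx / 2
    if (ob$laneRow - (ceiling(b) - 1) < 1 ||
        ob$laneRow + (ceiling(b) - 1) > .FRAME_ROWS)
      return(sprintf("laneRow %d puts the object outside the frame rows",
                     ob$laneRow))
  }
  TRUE
})

#' Construct and validate a scene configuration
#'
#' Unless `allowOverlap = TRUE`, the configuration is rejected when any two
#' objects would overlap (rows and columns simultaneously) in any frame:
#' the tracker's no-occlusion assumption must hold in fixtures unless
#' overlap is explicitly requested.
#'
#' @param nFrames Number of frames.
#' @param cows List of `list(template =, entryFrame =, laneRow =)`.
#' @param humans Like `cows`; `template` defaults to [humanTemplate()].
#' @param cameraHeightM Camera height (m), default 3.
#' @param noiseSdM Sensor noise SD (m), default 0.005.
#' @param seed Integer seed fixing the rendered sequence.
#' @param allowOverlap Permit overlapping objects (default `FALSE`).
#' @return A [SceneConfig-class] object.
#' @export
sceneConfig <- function(nFrames, cows = list(), humans = list(),
                        cameraHeightM = 3, noiseSdM = 0.005, seed = 1L,
                        allowOverlap = FALSE) {
  norm <- function(obj, default) {
    tpl <- if (is.null(obj$template)) default else obj$template
    list(template = tpl,
         entryFrame = as.integer(obj$entryFrame %||% 0L),
         laneRow = as.integer(obj$laneRow))
  }
  cows <- lapply(cows, norm, default = cowTemplate())
  humans <- lapply(humans, norm, default = humanTemplate())
  cfg <- new("SceneConfig", cameraHeightM = cameraHeightM,
             nFrames = as.integer(nFrames), cows = cows, humans = humans,
             noiseSdM = noiseSdM, seed = as.integer(seed),
             allowOverlap = isTRUE(allowOverlap))
  if (!cfg@allowOverlap) .checkNoOverlap(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Continuous body span of an object at frame t: columns (0-based,
## half-open) and the rows its footprint occupies.
.objectSpan <- function(obj, t) {
  tpl <- obj$template
  off <- -tpl@lengthPx + tpl@speedPxPerFrame * (t - obj$entryFrame)
  x0 <- max(0, off)
  x1 <- min(.FRAME_COLS, off + tpl@lengthPx)
  halfRows <- ceiling(tpl@widthPx / 2) - 1
  list(offset = off, x0 = x0, x1 = x1,
       y0 = obj$laneRow - halfRows - 1, y1 = obj$laneRow + halfRows,
       visible = t >= obj$entryFrame && x1 > x0)
}

.checkNoOverlap <- function(cfg) {
  objs <- c(cfg@cows, cfg@humans)
  if (length(objs) < 2L) return(invisible(TRUE))
  for (t in seq_len(cfg@nFrames) - 1L) {
    spans <- lapply(objs, .objectSpan, t = t)
    vis <- which(vapply(spans, `[[`, logical(1), "visible"))
    if (length(vis) < 2L) next
    for (a in vis) for (b in vis) {
      if (a >= b) next
      sa <- spans[[a]]; sb <- spans[[b]]
      if (sa$x0 < sb$x1 && sb$x0 < sa$x1 &&
          sa$y0 < sb$y1 && sb$y0 < sa$y1)
        stop(sprintf(
          "objects %d and %d overlap at frame %d; use allowOverlap = TRUE for stress scenes",
          a, b, t))
    }
  }
  invisible(TRUE)
}

## Evaluate RNG-dependent code under a local seed without disturbing the
## caller's RNG stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Render a synthetic scene into depth frames plus exact ground truth
#'
#' The floor is flat at `cameraHeightM` below the camera; each object is a
#' separable height surface (dorsal curve x elliptical cross-section)
#' translated horizontally at its template speed; per-pixel Gaussian noise
#' of SD `noiseSdM` is added to every distance and the result clamped at 0.
#' Ground truth lists, per frame, the tight box of each object's
#' nonzero-height footprint, its global track ID (cows first, then humans,
#' in configuration order), its label (`lame`/`sound` by the 1.2 m dorsal
#' peak convention, or `human`) and its visible footprint fraction.
#'
#' Rendering is deterministic given `config@seed`.
#'
#' @param config A [SceneConfig-class].
#' @return List with `frames` (list of [DepthFrame-class]), `truth`
#'   (ground-truth records as in [readGroundTruth()]) and `config`.
#' @export
#' @examples
#' sc <- sceneConfig(5, cows = list(list(template = cowTemplate(),
#'                                       entryFrame = 0, laneRow = 60)),
#'                   noiseSdM = 0)
#' out <- renderScene(sc)
#' length(out$frames)
renderScene <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  objs <- c(config@cows, config@humans)
  labels <- c(
    vapply(config@cows, function(o)
      if (o$template@peakHeightM < 1.2) "lame" else "sound", character(1)),
    rep("human", length(config@humans)))
  norms <- lapply(objs, function(o) .dorsalNorm(o$template))
  npx <- .FRAME_ROWS * .FRAME_COLS
  .withSeed(config@seed, {
    frames <- vector("list", config@nFrames)
    truth <- vector("list", config@nFrames)
    for (t in seq_len(config@nFrames) - 1L) {
      canvas <- matrix(0, .FRAME_ROWS, .FRAME_COLS)
      recs <- list()
      for (k in seq_along(objs)) {
        obj <- objs[[k]]
        tpl <- obj$template
        sp <- .objectSpan(obj, t)
        if (!sp$visible) next
        jj <- which(seq_len(.FRAME_COLS) - 0.5 > sp$offset &
                    seq_len(.FRAME_COLS) - 0.5 < sp$offset + tpl@lengthPx)
        if (length(jj) == 0L) next
        u <- jj - 0.5 - sp$offset
        dors <- tpl@peakHeightM * .dorsalShape(tpl, u) / norms[[k]]
        halfRows <- ceiling(tpl@widthPx / 2) - 1
        v <- -halfRows:halfRows
        cross <- sqrt(pmax(0, 1 - (v / (tpl@widthPx / 2))^2))
        rr <- obj$laneRow + v
        h <- outer(cross, dors)
        canvas[rr, jj] <- pmax(canvas[rr, jj], h)
        recs[[length(recs) + 1L]] <- list(
          box = c(min(jj) - 1, min(rr) - 1, max(jj), max(rr)),
          track_id = k, label = labels[[k]],
          visibility = length(jj) / tpl@lengthPx)
      }
      depth <- config@cameraHeightM - canvas
      if (config@noiseSdM > 0)
        depth <- depth + matrix(stats::rnorm(npx, sd = config@noiseSdM),
                                .FRAME_ROWS, .FRAME_COLS)
      depth <- pmax(depth, 0)
      frames[[t + 1L]] <- depthFrame(depth, index = t, session = "synthetic")
      truth[[t + 1L]] <- list(frame = t, objects = recs)
    }
    list(frames = frames, truth = truth, config = config)
  })
}

#' Generate a labelled benchmark suite of single-cow scenes
#'
#' Builds `nLame + nSound` cows with dorsal peaks on either side of the
#' 1.2 m boundary (lame: uniform in 0.95--1.05 m with pronounced arch;
#' sound: uniform in 1.35--1.45 m, near-straight back), each traversing its
#' own seeded scene in one of two alternating lanes, and splits them by cow
#' into train and test collections. Labels follow the template peak-height
#' convention exactly.
#'
#' @param seed Integer master seed; fixes templates, lane assignment, scene
#'   seeds and the split.
#' @param nLame,nSound Cow counts per class (each at least 1).
#' @param noiseSdM Sensor noise SD for every scene (m), default 0.01.
#' @param trainFraction Fraction of cows (per class) in the train split.
#' @return List with `train` and `test`, each a list of
#'   `list(config, cowId, label)`, plus `labels` (per cowId) and `seed`.
#' @export
makeBenchmarkSuite <- function(seed, nLame, nSound, noiseSdM = 0.01,
                               trainFraction = 0.7) {
  stopifnot(nLame >= 1, nSound >= 1)
  .withSeed(seed, {
    n <- nLame + nSound
    lame <- c(rep(TRUE, nLame), rep(FALSE, nSound))
    peaks <- ifelse(lame, stats::runif(n, 0.95, 1.05),
                          stats::runif(n, 1.35, 1.45))
    arch <- ifelse(lame, stats::runif(n, 0.4, 0.8),
                         stats::runif(n, 0, 0.15))
    sceneSeeds <- sample.int(.Machine$integer.max - 1L, n)
    lanes <- rep(c(40L, 92L), length.out = n)
    scenes <- vector("list", n)
    for (i in seq_len(n)) {
      tpl <- cowTemplate(peakHeightM = peaks[i], arch = arch[i])
      travel <- ceiling((tpl@lengthPx + .FRAME_COLS) / tpl@speedPxPerFrame)
      scenes[[i]] <- list(
        config = sceneConfig(travel + 1L,
                             cows = list(list(template = tpl,
                                              entryFrame = 0L,
                                              laneRow = lanes[i])),
                             noiseSdM = noiseSdM, seed = sceneSeeds[i]),
        cowId = i,
        label = if (lame[i]) "lame" else "sound")
    }
    pickTrain <- function(idx) {
      k <- ceiling(trainFraction * length(idx))
      sort(sample(idx, k))
    }
    trainIdx <- c(pickTrain(which(lame)), pickTrain(which(!lame)))
    list(train = scenes[sort(trainIdx)],
         test = scenes[setdiff(seq_len(n), trainIdx)],
         labels = ifelse(lame, "lame", "sound"),
         seed = as.integer(seed))
  })
}
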