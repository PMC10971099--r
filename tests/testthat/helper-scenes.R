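# Shared fixture builders: every fixture is generated in code at test time.

# one cow traversing its own scene
oneCowScene <- function(peak = 1.4, arch = 0, noise = 0, seed = 1L,
                        laneRow = 60L, nFrames = 45L) {
  sceneConfig(nFrames,
              cows = list(list(template = cowTemplate(peakHeightM = peak,
                                                      arch = arch),
                               entryFrame = 0L, laneRow = laneRow)),
              noiseSdM = noise, seed = seed)
}

# staggered multi-cow scene in two lanes, no occlusion
multiCowScene <- function(peaks, archs = rep(0, length(peaks)),
                          noise = 0.005, seed = 1L, nFrames = 200L,
                          spacing = 35L) {
  lanes <- c(40L, 92L)
  cows <- lapply(seq_along(peaks), function(k)
    list(template = cowTemplate(peakHeightM = peaks[k], arch = archs[k]),
         entryFrame = (k - 1L) * spacing,
         laneRow = lanes[(k - 1L) %% 2L + 1L]))
  sceneConfig(nFrames, cows = cows, noiseSdM = noise, seed = seed)
}

# brute-force IOU by counting unit pixels (independent oracle for boxIOU)
pixelCountIOU <- function(a, b) {
  cells <- function(box) {
    if (box[3] <= box[1] || box[4] <= box[2]) return(character(0))
    g <- expand.grid(x = seq(box[1], box[3] - 1), y = seq(box[2], box[4] - 1))
    paste(g$x, g$y)
  }
  ca <- cells(a); cb <- cells(b)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

# run detection + filter + tracking on a rendered scene
trackScene <- function(scene, cameraHeightM = 3, fgDeltaM = 0.1,
                       minArea = 50, threshold = 4000,
                       iouThreshold = 0.5) {
  regions <- detectFrames(scene$frames, function(fr)
    referenceDetect(fr, cameraHeightM, fgDeltaM, minArea))
  filtered <- lapply(regions, noiseFilter, threshold = threshold)
  run <- runTracker(filtered, iouThreshold = iouThreshold)
  list(regions = regions, filtered = filtered, run = run,
       predictions = predictionsFromRun(filtered, run$assignments))
}

# synthetic instance region with a prescribed pixel sum (square mask of
# constant depth), for boundary-case tests of the noise filter
regionWithSum <- function(total, side = 20L) {
  depth <- total / side^2
  vals <- matrix(0, 132, 176)
  vals[1:side, 1:side] <- depth
  fr <- depthFrame(vals, index = 0L)
  mask <- matrix(FALSE, 132, 176)
  mask[1:side, 1:side] <- TRUE
  instanceRegion(fr, mask)
}
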