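test_that("connected components agree with a brute-force flood fill", {
  floodComponents <- function(mask) {
    lab <- matrix(0L, nrow(mask), ncol(mask))
    nxt <- 0L
    for (s in which(mask)) {
      if (lab[s] != 0L) next
      nxt <- nxt + 1L
      queue <- s
      lab[s] <- nxt
      while (length(queue)) {
        p <- queue[1]; queue <- queue[-1]
        r <- (p - 1L) %% nrow(mask) + 1L
        c <- (p - 1L) %/% nrow(mask) + 1L
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; cc <- c + dc
          if (rr < 1 || cc < 1 || rr > nrow(mask) || cc > ncol(mask)) next
          q <- (cc - 1L) * nrow(mask) + rr
          if (mask[q] && lab[q] == 0L) { lab[q] <- nxt; queue <- c(queue, q) }
        }
      }
    }
    lab
  }
  set.seed(7)
  for (i in 1:5) {
    mask <- matrix(runif(20 * 25) < 0.35, 20, 25)
    comps <- connectedComponents(mask)
    lab <- floodComponents(mask)
    expect_length(comps, max(lab))
    # every returned mask is exactly one flood-fill component
    for (cm in comps) {
      ids <- unique(lab[cm])
      expect_length(ids, 1)
      expect_identical(sum(cm), sum(lab == ids))
    }
    # diagonal-only neighbours join under 8- but not 4-connectivity
  }
  diagonal <- matrix(FALSE, 5, 5)
  diagonal[cbind(1:3, 1:3)] <- TRUE
  expect_length(connectedComponents(diagonal, connectivity = 8), 1)
  expect_length(connectedComponents(diagonal, connectivity = 4), 3)
})

test_that("the reference detector finds nothing in an empty scene", {
  out <- renderScene(sceneConfig(2, noiseSdM = 0))
  expect_length(referenceDetect(out$frames[[1]]), 0)
})

test_that("a noise-free cow yields exactly one mask equal to its footprint", {
  out <- renderScene(oneCowScene(noise = 0))
  k <- 23  # cow centred, fully visible
  masks <- referenceDetect(out$frames[[k]], fgDeltaM = 1e-9)
  expect_length(masks, 1)
  footprint <- (3 - depthValues(out$frames[[k]])) > 0
  expect_identical(masks[[1]], footprint)
})

test_that("a cow and a human give two masks before filtering", {
  sc <- sceneConfig(40,
    cows = list(list(template = cowTemplate(), entryFrame = 0L,
                     laneRow = 40L)),
    humans = list(list(entryFrame = 0L, laneRow = 110L)),
    noiseSdM = 0)
  out <- renderScene(sc)
  k <- 23
  expect_length(out$truth[[k]]$objects, 2)
  masks <- referenceDetect(out$frames[[k]])
  expect_length(masks, 2)
  # largest first
  expect_gte(sum(masks[[1]]), sum(masks[[2]]))
})

test_that("the pixel-sum filter keeps >4000 and rejects <=4000, strictly", {
  regions <- list(regionWithSum(4500), regionWithSum(3999),
                  regionWithSum(4000))
  out <- noiseFilter(regions)
  expect_identical(sapply(out, regionKind), c("cow", "rejected", "rejected"))
  # order preserved and idempotent
  expect_identical(sapply(out, pixelSum), sapply(regions, pixelSum))
  expect_identical(sapply(noiseFilter(out), regionKind),
                   sapply(out, regionKind))
})

test_that("filtered synthetic detections recover the ground-truth cow count", {
  sc <- sceneConfig(60,
    cows = list(list(template = cowTemplate(), entryFrame = 0L,
                     laneRow = 40L)),
    humans = list(list(entryFrame = 5L, laneRow = 110L)),
    noiseSdM = 0)
  out <- renderScene(sc)
  regions <- detectFrames(out$frames)
  filtered <- lapply(regions, noiseFilter)
  for (k in seq_along(out$frames)) {
    kept <- sum(vapply(filtered[[k]], regionKind, character(1)) == "cow")
    objs <- out$truth[[k]]$objects
    gtCows <- if (length(objs)) sum(vapply(objs, function(o)
      o$label != "human" && o$visibility >= 0.25, logical(1))) else 0L
    if (length(filtered[[k]]) == 0) expect_identical(gtCows + 0L, 0L)
    else expect_gte(kept, gtCows)  # humans never kept, cows kept once visible
    for (r in filtered[[k]]) {
      hums <- Filter(function(o) o$label == "human", out$truth[[k]]$objects)
      if (length(hums) && boxIOU(boundingBox(r), hums[[1]]$box) > 0.3)
        expect_identical(regionKind(r), "rejected")
    }
  }
})

test_that("masked depth extraction multiplies exactly and only by the mask", {
  set.seed(11)
  vals <- matrix(runif(132 * 176, 0.5, 3), 132, 176)
  fr <- depthFrame(vals)
  allMask <- matrix(TRUE, 132, 176)
  expect_identical(extractDepthRegion(fr, instanceRegion(fr, allMask)), vals)
  noneMask <- matrix(FALSE, 132, 176)
  r0 <- new("InstanceRegion", frameIndex = 0L, mask = noneMask,
            box = c(0, 0, 0, 0), pixelSum = 0, kind = "cow")
  expect_true(all(extractDepthRegion(fr, r0) == 0))
  randMask <- matrix(runif(132 * 176) < 0.2, 132, 176)
  got <- extractDepthRegion(fr, instanceRegion(fr, randMask))
  expect_identical(got != 0, randMask)       # values are never 0 inside
  expect_identical(got[randMask], vals[randMask])
})

test_that("external mask rasters feed the pluggable detector", {
  out <- renderScene(oneCowScene(noise = 0))
  k <- 23
  mask <- referenceDetect(out$frames[[k]])[[1]]
  dir <- tempfile(); dir.create(dir)
  png::writePNG(mask * 1, file.path(dir, sprintf("%d_0.png", k - 1L)))
  det <- masksDetector(dir)
  got <- det(out$frames[[k]])
  expect_length(got, 1)
  expect_identical(got[[1]], mask)
  expect_length(det(out$frames[[1]]), 0)
})
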