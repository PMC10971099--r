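test_that("boxIOU matches brute-force pixel counting on random box pairs", {
  expect_equal(boxIOU(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(boxIOU(c(0, 0, 10, 10), c(20, 0, 30, 10)), 0)
  expect_equal(boxIOU(c(0, 0, 10, 10), c(5, 0, 15, 10)), 50 / 150)
  expect_error(boxIOU(c(0, 0, 0, 10), c(0, 0, 5, 5)), "degenerate")

  set.seed(123)
  for (i in 1:1000) {
    a <- c(sort(sample(0:12, 2)), sort(sample(0:12, 2)))[c(1, 3, 2, 4)]
    b <- c(sort(sample(0:12, 2)), sort(sample(0:12, 2)))[c(1, 3, 2, 4)]
    if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2]) next
    expect_equal(boxIOU(a, b), pixelCountIOU(a, b), tolerance = 1e-12)
  }
})

test_that("cold start assigns sequential IDs and perfect overlap retains them", {
  fr <- depthFrame(matrix(3, 132, 176))
  mk <- function(r0, c0) {
    m <- matrix(FALSE, 132, 176)
    m[r0:(r0 + 20), c0:(c0 + 30)] <- TRUE
    instanceRegion(fr, m)
  }
  st <- trackerState()
  s1 <- trackStep(st, 0L, list(mk(10, 10), mk(80, 10)))
  expect_identical(s1$assignments, c(1L, 2L))
  s2 <- trackStep(s1$state, 1L, list(mk(80, 10), mk(10, 10)))
  expect_identical(s2$assignments, c(2L, 1L))
  expect_identical(s2$state@nextId, 3L)
})

test_that("one-to-one matching holds within every frame", {
  out <- renderScene(multiCowScene(c(1.4, 1.0, 1.35), nFrames = 130L,
                                   seed = 2L))
  tk <- trackScene(out)
  a <- tk$run$assignments
  a <- a[!is.na(a$track_id), ]
  dup <- tapply(a$track_id, a$frame_index, anyDuplicated)
  expect_true(all(dup == 0))
})

test_that("tracking a no-occlusion scene matches ground truth with no switches", {
  out <- renderScene(multiCowScene(c(1.4, 1.0, 1.35), nFrames = 130L,
                                   seed = 3L))
  tk <- trackScene(out)
  expect_length(tk$run$tracks, 3)
  s <- scoreRun(tk$predictions, out$truth)
  expect_identical(s$tracking$IDS, 0L)
  expect_identical(s$tracking$FN, 0L)
  expect_identical(s$tracking$FP, 0L)
  # assignments equal ground truth up to relabeling: each track maps to
  # exactly one ground-truth identity
  labels <- assignTrackLabels(tk$run$tracks, out$truth)
  expect_false(anyNA(labels))
})

test_that("tracking is deterministic on identical inputs", {
  out <- renderScene(multiCowScene(c(1.4, 1.0), nFrames = 100L, seed = 4L))
  t1 <- trackScene(out)
  t2 <- trackScene(out)
  expect_identical(t1$run$assignments, t2$run$assignments)
})

test_that("a miss closes a track after the patience window", {
  fr <- depthFrame(matrix(3, 132, 176))
  m <- matrix(FALSE, 132, 176); m[10:40, 10:60] <- TRUE
  r <- instanceRegion(fr, m)
  st <- trackStep(trackerState(patience = 1L), 0L, list(r))$state
  st <- trackStep(st, 1L, list())$state          # miss -> closed
  s3 <- trackStep(st, 2L, list(r))
  expect_identical(s3$assignments, 2L)           # new ID, old track closed
  expect_length(collectTracks(s3$state), 2)
})

test_that("archived tracks round-trip through per-ID folders", {
  out <- renderScene(multiCowScene(c(1.4, 1.0), nFrames = 100L, seed = 5L,
                                   noise = 0))
  tk <- trackScene(out)
  dir <- tempfile()
  archiveTracks(tk$run$tracks, out$frames, dir)
  expect_setequal(list.dirs(dir, recursive = FALSE, full.names = FALSE),
                  as.character(sapply(tk$run$tracks, trackId)))
  back <- loadTracks(dir)
  expect_length(back, length(tk$run$tracks))
  for (k in seq_along(back)) {
    orig <- tk$run$tracks[[k]]
    expect_identical(trackId(back[[k]]), trackId(orig))
    expect_identical(trackFrames(back[[k]]), trackFrames(orig))
    for (j in seq_along(trackRegions(orig))) {
      expect_identical(regionMask(trackRegions(back[[k]])[[j]]),
                       regionMask(trackRegions(orig)[[j]]))
      expect_equal(pixelSum(trackRegions(back[[k]])[[j]]),
                   pixelSum(trackRegions(orig)[[j]]), tolerance = 1e-6)
    }
  }
  # refuses to overwrite a non-empty ID folder without force
  expect_error(archiveTracks(tk$run$tracks, out$frames, dir), "force")
  expect_silent(archiveTracks(tk$run$tracks, out$frames, dir, force = TRUE))
})

test_that("an empty track set archives to an empty manifest", {
  dir <- tempfile()
  archiveTracks(list(), list(), dir)
  expect_length(loadTracks(dir), 0)
})
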