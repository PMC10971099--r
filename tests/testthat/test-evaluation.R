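test_that("detection accuracy follows its count formula with half-up rounding", {
  expect_equal(detectionAccuracy(1273, 0, 4, 0), 99.69)
  expect_equal(detectionAccuracy(10, 0, 0, 0), 100)
  expect_equal(detectionAccuracy(1, 1, 1, 1), 50)
  expect_error(detectionAccuracy(0, 0, 0, 0), "positive total")
  expect_error(detectionAccuracy(-1, 0, 2, 0), "non-negative")
})

test_that("MOTA follows its count formula and is bounded above by 100", {
  expect_equal(mota(1297, 0, 2, 3), 99.61)
  expect_equal(mota(1843, 1, 0, 1), 99.89)
  expect_equal(mota(100, 0, 0, 0), 100)
  expect_equal(mota(10, 20, 0, 0), -100)  # unbounded below
  expect_error(mota(0, 0, 0, 0), "GT > 0")
})

test_that("MOTA strictly decreases in each error count at fixed GT", {
  base <- mota(500, 2, 3, 1)
  expect_lt(mota(500, 3, 3, 1), base)
  expect_lt(mota(500, 2, 4, 1), base)
  expect_lt(mota(500, 2, 3, 2), base)
})

test_that("session summaries use the unweighted mean across sessions", {
  tk <- exampleSessionCounts("tracking")
  s <- sessionSummary(tk, "mota")
  expect_equal(s$perSession, tk$reported_pct)
  expect_equal(s$average, 99.92)
  expect_equal(sessionSummary(88)$average, 88)
  expect_equal(sessionSummary(rep(100, 4))$average, 100)
})

test_that("rounding reports half away from zero", {
  expect_equal(roundHalfUp(99.615), 99.62)
  expect_equal(roundHalfUp(99.6849), 99.68)
  expect_equal(roundHalfUp(2.5, 0), 3)
})

test_that("a perfect synthetic run scores 100% detection and MOTA", {
  out <- renderScene(multiCowScene(c(1.4, 1.0), nFrames = 100L, seed = 6L))
  tk <- trackScene(out)
  s <- scoreRun(tk$predictions, out$truth)
  expect_identical(s$detection[c("FP", "FN")], list(FP = 0L, FN = 0L))
  expect_identical(s$tracking[c("FP", "FN", "IDS")],
                   list(FP = 0L, FN = 0L, IDS = 0L))
  expect_equal(s$tracking$mota, 100)
})

test_that("injected spurious regions lower detection accuracy arithmetically", {
  # 1000 frames, one ground-truth cow each, a spurious box every 100 frames
  gtBox <- c(20, 20, 120, 80)
  farBox <- c(140, 100, 170, 130)
  truth <- lapply(0:999, function(k) list(frame = k, objects = list(
    list(box = gtBox, track_id = 1L, label = "sound", visibility = 1))))
  preds <- lapply(0:999, function(k) {
    objs <- list(list(box = gtBox, track_id = 1L, kind = "cow"))
    if (k %% 100 == 0)
      objs <- c(objs, list(list(box = farBox, track_id = 99L, kind = "cow")))
    list(frame = k, objects = objs)
  })
  s <- scoreRun(preds, truth)
  expect_identical(s$detection$TP, 1000L)
  expect_identical(s$detection$FP, 10L)
  expect_equal(s$detection$accuracy, 99.01)
})

test_that("swapping two track IDs mid-scene counts two identity switches", {
  boxA <- c(0, 10, 60, 60); boxB <- c(100, 70, 170, 120)
  truth <- lapply(0:9, function(k) list(frame = k, objects = list(
    list(box = boxA, track_id = 1L, label = "sound", visibility = 1),
    list(box = boxB, track_id = 2L, label = "lame", visibility = 1))))
  preds <- lapply(0:9, function(k) {
    ids <- if (k < 5) c(1L, 2L) else c(2L, 1L)
    list(frame = k, objects = list(
      list(box = boxA, track_id = ids[1], kind = "cow"),
      list(box = boxB, track_id = ids[2], kind = "cow")))
  })
  s <- scoreRun(preds, truth)
  expect_identical(s$tracking$IDS, 2L)
  expect_identical(s$tracking$FN, 0L)
  expect_identical(s$tracking$FP, 0L)
})

test_that("low-visibility ground truth is ignored, not penalised", {
  truth <- list(list(frame = 0L, objects = list(
    list(box = c(0, 20, 30, 70), track_id = 1L, label = "sound",
         visibility = 0.1))))
  # undetected partial cow: no miss
  s1 <- scoreRun(list(list(frame = 0L, objects = list())), truth)
  expect_identical(s1$detection$FN, 0L)
  expect_identical(s1$tracking$GT, 0L)
  # detected partial cow: no false positive either
  s2 <- scoreRun(list(list(frame = 0L, objects = list(
    list(box = c(0, 20, 30, 70), track_id = 5L, kind = "cow")))), truth)
  expect_identical(s2$detection$FP, 0L)
  expect_identical(s2$tracking$FP, 0L)
})

test_that("scoring demands ground truth for every scored frame", {
  preds <- list(list(frame = 3L, objects = list()))
  expect_error(scoreRun(preds, list(list(frame = 0L, objects = list()))),
               "frame 3")
})
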