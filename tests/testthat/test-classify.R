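# quick in-memory dataset built from noisy dorsal curves (no rendering)
profileDataset <- function(nLame, nSound, split, seed = 1L, noise = 0.01) {
  set.seed(seed)
  n <- nLame + nSound
  lame <- rep(c(TRUE, FALSE), c(nLame, nSound))
  feats <- t(vapply(seq_len(n), function(i) {
    peak <- if (lame[i]) runif(1, 0.95, 1.05) else runif(1, 1.35, 1.45)
    dorsalProfile(cowTemplate(peakHeightM = peak, arch = 0.3)) +
      rnorm(176, sd = noise)
  }, numeric(176)))
  labelledDataset(pmax(feats, 1e-6), ifelse(lame, "lame", "sound"),
                  split, seq_len(n))
}

test_that("1-nearest-neighbour memorises identical train and test data", {
  ds <- profileDataset(6, 6, split = rep(c("train", "test"),
                                         length.out = 12), seed = 2L)
  # duplicate the train rows as the test split
  tr <- which(datasetSplit(ds) == "train")
  ds2 <- labelledDataset(rbind(datasetFeatures(ds)[tr, ],
                               datasetFeatures(ds)[tr, ]),
                         rep(datasetLabels(ds)[tr], 2),
                         rep(c("train", "test"), each = length(tr)),
                         rep(seq_along(tr), 2))
  rep1 <- trainEval(ds2, "KNN", seed = 1, k = 1)
  expect_equal(trainAccuracy(rep1), 100)
  expect_equal(testAccuracy(rep1), 100)
})

test_that("classifier reports are internally consistent and reproducible", {
  ds <- profileDataset(10, 14, split = rep(c("train", "test"),
                                           c(16, 8)), seed = 3L)
  for (m in c("RF", "KNN", "DT")) {
    r <- trainEval(ds, m, seed = 9)
    expect_identical(sum(confusionMatrix(r)), sum(datasetSplit(ds) == "test"))
    expect_equal(testAccuracy(r),
                 100 * sum(diag(confusionMatrix(r))) / sum(confusionMatrix(r)))
    r2 <- trainEval(ds, m, seed = 9)
    expect_identical(reportPredictions(r), reportPredictions(r2))
  }
})

test_that("separable classes are recovered by all three models", {
  ds <- profileDataset(20, 20, split = rep(c("train", "test"),
                                           c(26, 14)), seed = 4L)
  for (m in c("RF", "KNN", "DT"))
    expect_gte(testAccuracy(trainEval(ds, m, seed = 1)), 95)
})

test_that("permuted labels drop test accuracy to the majority-class rate", {
  ds <- profileDataset(120, 180, split = rep(c("train", "test"),
                                             c(200, 100)), seed = 5L)
  set.seed(99)
  perm <- labelledDataset(datasetFeatures(ds),
                          sample(as.character(datasetLabels(ds))),
                          datasetSplit(ds), ds@cowId)
  r <- trainEval(perm, "RF", seed = 1)
  majority <- 100 * max(table(datasetLabels(perm)[datasetSplit(perm) == "test"])) / 100
  expect_lt(abs(testAccuracy(r) - majority), 15)
})

test_that("a single-class training split is a configuration error", {
  ds <- profileDataset(5, 5, split = c(rep("train", 5), rep("test", 5)),
                       seed = 6L)
  expect_error(trainEval(ds, "RF"), "both classes")
})

test_that("the 1.2 m baseline predicts by profile maximum and is monotone", {
  ds <- profileDataset(10, 10, split = rep(c("train", "test"), 10), seed = 7L)
  r <- thresholdBaseline(ds)
  expect_equal(testAccuracy(r), 100)
  maxima <- apply(datasetFeatures(ds), 1, max)
  expect_identical(reportPredictions(r)$predicted[order(reportPredictions(r)$cowId)],
                   unname(ifelse(maxima < 1.2, "lame", "sound")))
  # raising the cutoff never decreases the number of lame predictions
  nLame <- sapply(c(1.0, 1.2, 1.4, 1.6), function(cut)
    sum(reportPredictions(thresholdBaseline(ds, cut))$predicted == "lame"))
  expect_true(all(diff(nLame) >= 0))
})

test_that("per-cow majority vote aggregates frame predictions", {
  ds <- profileDataset(4, 4, split = rep(c("train", "test"), 4), seed = 8L)
  r <- thresholdBaseline(ds)
  agg <- cowMajorityVote(r)
  expect_identical(nrow(agg), sum(datasetSplit(ds) == "test"))
  expect_true(all(agg$correct))
})

test_that("all-zero feature rows are rejected at construction", {
  feats <- rbind(dorsalProfile(cowTemplate()), rep(0, 176))
  expect_error(labelledDataset(feats, c("sound", "lame"),
                               c("train", "test"), 1:2),
               "all-zero")
})
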