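#' Label tracks by majority vote against ground truth
#'
#' For every observation of a track, the ground-truth object with the
#' highest box IOU (at or above the threshold) casts a vote with its
#' label; the track takes the majority label. Tracks with no matching
#' ground truth get `NA`.
#'
#' @param tracks List of [Track-class].
#' @param truth Ground-truth records (see [readGroundTruth()]).
#' @param iouThreshold Minimum IOU for a vote, default 0.5.
#' @return Named character vector, one label per track ID.
#' @export
assignTrackLabels <- function(tracks, truth, iouThreshold = 0.5) {
  byFrame <- stats::setNames(truth,
    vapply(truth, `[[`, integer(1), "frame"))
  out <- vapply(tracks, function(tr) {
    votes <- character(0)
    for (k in seq_along(tr@frameIndices)) {
      rec <- byFrame[[as.character(tr@frameIndices[k])]]
      if (is.null(rec) || length(rec$objects) == 0L) next
      ious <- vapply(rec$objects, function(o)
        boxIOU(tr@regions[[k]]@box, o$box), numeric(1))
      if (max(ious) >= iouThreshold)
        votes <- c(votes, rec$objects[[which.max(ious)]]$label)
    }
    if (length(votes) == 0L) return(NA_character_)
    names(sort(table(votes), decreasing = TRUE))[1L]
  }, character(1))
  stats::setNames(out, vapply(tracks, trackId, integer(1)))
}

.splitData <- function(dataset, which) {
  sel <- dataset@split == which
  list(x = dataset@features[sel, , drop = FALSE],
       y = factor(dataset@labels[sel], levels = c("lame", "sound")),
       cowId = dataset@cowId[sel])
}

.accuracyPct <- function(truth, pred)
  100 * mean(as.character(pred) == as.character(truth))

.confusion <- function(truth, pred) {
  tab <- table(truth = factor(truth, levels = c("lame", "sound")),
               prediction = factor(pred, levels = c("lame", "sound")))
  matrix(as.integer(tab), 2L, 2L,
         dimnames = list(truth = c("lame", "sound"),
                         prediction = c("lame", "sound")))
}

.makeReport <- function(model, dataset, trainPred, testPred, params) {
  tr <- .splitData(dataset, "train")
  te <- .splitData(dataset, "test")
  cm <- .confusion(te$y, testPred)
  preds <- rbind(
    data.frame(cowId = tr$cowId, truth = as.character(tr$y),
               predicted = as.character(trainPred),
               correct = as.character(trainPred) == as.character(tr$y),
               split = "train"),
    data.frame(cowId = te$cowId, truth = as.character(te$y),
               predicted = as.character(testPred),
               correct = as.character(testPred) == as.character(te$y),
               split = "test"))
  new("ClassifierReport", model = model,
      trainAccuracy = .accuracyPct(tr$y, trainPred),
      testAccuracy = .accuracyPct(te$y, testPred),
      confusion = cm, predictions = preds, params = params)
}

#' Train and evaluate a lameness classifier
#'
#' Fits one of the three supported classical models on the train split of
#' a [LabelledDataset-class] and evaluates on both splits: random forest
#' (`"RF"`, [randomForest::randomForest()]), k-nearest neighbours
#' (`"KNN"`, [class::knn()]) or a decision tree (`"DT"`,
#' [rpart::rpart()], grown to full depth). The seed fixes all stochastic
#' fitting, making reports reproducible bit for bit.
#'
#' @param dataset A [LabelledDataset-class]; the train split must contain
#'   both classes.
#' @param model `"RF"`, `"KNN"` or `"DT"`.
#' @param seed Integer seed.
#' @param ntree Random-forest tree count, default 100.
#' @param k Neighbour count for KNN, default 5.
#' @param maxdepth Decision-tree depth cap, default 30 (rpart's maximum,
#'   i.e. effectively unlimited); the tree is grown with no complexity
#'   pruning.
#' @return A [ClassifierReport-class].
#' @export
trainEval <- function(dataset, model = c("RF", "KNN", "DT"), seed = 1L,
                      ntree = 100L, k = 5L, maxdepth = 30L) {
  model <- match.arg(model)
  stopifnot(is(dataset, "LabelledDataset"))
  tr <- .splitData(dataset, "train")
  te <- .splitData(dataset, "test")
  if (length(unique(tr$y)) < 2L)
    stop("training split must contain both classes")
  params <- list(seed = as.integer(seed))
  .withSeed(seed, {
    if (model == "RF") {
      params$ntree <- as.integer(ntree)
      fit <- randomForest::randomForest(x = tr$x, y = tr$y,
                                        ntree = as.integer(ntree))
      trainPred <- stats::predict(fit, tr$x)
      testPred <- stats::predict(fit, te$x)
    } else if (model == "KNN") {
      params$k <- as.integer(k)
      trainPred <- class::knn(tr$x, tr$x, tr$y, k = as.integer(k))
      testPred <- class::knn(tr$x, te$x, tr$y, k = as.integer(k))
    } else {
      params$maxdepth <- as.integer(maxdepth)
      df <- data.frame(label = tr$y, tr$x, check.names = FALSE)
      fit <- rpart::rpart(label ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            cp = 0, minsplit = 2L, xval = 0L,
                            maxdepth = as.integer(maxdepth)))
      trainPred <- stats::predict(fit,
        data.frame(tr$x, check.names = FALSE), type = "class")
      testPred <- stats::predict(fit,
        data.frame(te$x, check.names = FALSE), type = "class")
    }
    .makeReport(model, dataset, trainPred, testPred, params)
  })
}

#' Transparent 1.2 m backbone-height baseline
#'
#' The field heuristic behind the labels: lame cows carry their highest
#' dorsal point below about 1.2 m, sound cows above it. Predicts `lame`
#' iff `max(profile) < cutoff`, with no fitting; reported in the same
#' shape as [trainEval()]. Raising the cutoff can only turn `sound`
#' predictions into `lame` ones (monotone in the cutoff).
#'
#' @param dataset A [LabelledDataset-class].
#' @param cutoff Height cutoff in metres (> 0), default 1.2.
#' @return A [ClassifierReport-class] with model `"baseline"`.
#' @export
thresholdBaseline <- function(dataset, cutoff = 1.2) {
  stopifnot(is(dataset, "LabelledDataset"), cutoff > 0)
  predictSplit <- function(x)
    factor(ifelse(apply(x, 1L, max) < cutoff, "lame", "sound"),
           levels = c("lame", "sound"))
  tr <- .splitData(dataset, "train")
  te <- .splitData(dataset, "test")
  .makeReport("baseline", dataset, predictSplit(tr$x), predictSplit(te$x),
              list(cutoff = cutoff))
}

#' Per-cow majority vote over a report's frame predictions
#'
#' Optional aggregation layer (an extension beyond per-frame accuracy):
#' each cow's predicted class is the majority over its frames.
#'
#' @param report A [ClassifierReport-class].
#' @param split `"test"` (default) or `"train"`.
#' @return Data frame with `cowId`, `truth`, `predicted`, `correct`.
#' @export
cowMajorityVote <- function(report, split = "test") {
  p <- report@predictions
  p <- p[p$split == split, , drop = FALSE]
  out <- do.call(rbind, lapply(split(p, p$cowId), function(g) {
    data.frame(cowId = g$cowId[1L], truth = g$truth[1L],
               predicted = names(sort(table(g$predicted),
                                      decreasing = TRUE))[1L])
  }))
  out$correct <- out$truth == out$predicted
  rownames(out) <- NULL
  out
}
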