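test_that("full-width selection keeps exactly the boxes spanning 176 columns", {
  fr <- depthFrame(matrix(2, 132, 176))
  mk <- function(c0, c1) {
    m <- matrix(FALSE, 132, 176)
    m[30:80, (c0 + 1):c1] <- TRUE
    instanceRegion(fr, m)
  }
  tr <- new("Track", trackId = 1L, frameIndices = c(0L, 1L, 2L),
            regions = list(mk(0, 176), mk(3, 176), mk(0, 170)))
  sel <- selectFullWidthFrames(tr)
  expect_identical(trackFrames(sel), 0L)
  # all-partial track -> empty selection, flagged with a warning
  tr2 <- new("Track", trackId = 2L, frameIndices = 0L,
             regions = list(mk(3, 176)))
  expect_warning(ft <- featurizeTrack(tr2, list(fr)), "no full-width")
  expect_identical(nrow(ft$profiles), 0L)
})

test_that("height transform is distance minus depth, clamped and masked", {
  md <- matrix(0, 132, 176)
  mask <- matrix(FALSE, 132, 176)
  mask[10, 10:12] <- TRUE
  md[10, 10:12] <- c(1.6, 2.8, 3.0)   # below floor -> clamped to 0
  h <- heightTransform(md, distance = 2.8, mask = mask)
  expect_equal(h[10, 10:12], c(1.2, 0, 0))
  expect_true(all(h[!mask] == 0))
})

test_that("gaussian kernels are normalised and leave constants unchanged", {
  for (sg in c(0.5, 1, 2.5)) {
    k <- gaussianKernel(sg)
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_identical(dim(k), rep(as.integer(2 * ceiling(3 * sg) + 1), 2))
  }
  const <- matrix(1.7, 40, 50)
  expect_equal(gaussianSmooth(const, 1), const, tolerance = 1e-12)
})

test_that("an interior impulse spreads to the kernel and preserves mass", {
  f <- matrix(0, 41, 41)
  f[21, 21] <- 1
  sm <- gaussianSmooth(f, 1)
  k <- gaussianKernel(1)
  expect_equal(sm[21, 21], k[4, 4], tolerance = 1e-12)
  expect_equal(sm[18:24, 18:24], k, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
})

test_that("smoothing never increases the maximum", {
  set.seed(21)
  for (i in 1:5) {
    f <- matrix(runif(132 * 176), 132, 176)
    expect_lte(max(gaussianSmooth(f, runif(1, 0.5, 2))), max(f))
  }
})

test_that("backbone profile is the per-column maximum", {
  toy <- rbind(c(1, 0, 2, 0), c(0, 3, 0, 0), c(1, 1, 1, 4))
  expect_equal(backboneProfile(toy), c(1, 3, 2, 4))
  f <- matrix(0, 132, 176)
  f[60, 10] <- 1.3
  p <- backboneProfile(f)
  expect_length(p, 176)
  expect_equal(p[10], 1.3)
  expect_true(all(p[-10] == 0))
  # brute-force equivalence on random grids
  set.seed(31)
  for (i in 1:5) {
    g <- matrix(rnorm(132 * 176), 132, 176)
    slow <- vapply(seq_len(ncol(g)), function(j) {
      m <- -Inf
      for (r in seq_len(nrow(g))) if (g[r, j] > m) m <- g[r, j]
      m
    }, numeric(1))
    expect_equal(backboneProfile(g), slow)
  }
})

test_that("unsmoothed noise-free profiles equal the dorsal curve to 1e-6", {
  tpl <- cowTemplate(peakHeightM = 1.33, arch = 0.5)
  out <- renderScene(oneCowScene(peak = 1.33, arch = 0.5, noise = 0))
  tk <- trackScene(out)
  tr <- tk$run$tracks[[1]]
  sel <- selectFullWidthFrames(tr)
  expect_gte(length(trackFrames(sel)), 1)
  k <- which(sapply(out$frames, frameIndex) == trackFrames(sel)[1])
  masked <- extractDepthRegion(out$frames[[k]], trackRegions(sel)[[1]])
  h <- heightTransform(masked, distance = 3,
                       mask = regionMask(trackRegions(sel)[[1]]))
  expect_equal(backboneProfile(h), dorsalProfile(tpl), tolerance = 1e-6)
})

test_that("sound and lame cows straddle 1.2 m and repeat deterministically", {
  for (case in list(list(peak = 1.4, cmp = `>`), list(peak = 1.1, cmp = `<`))) {
    out <- renderScene(oneCowScene(peak = case$peak, arch = 0.5,
                                   noise = 0.005, seed = 8L))
    tk <- trackScene(out)
    ft <- featurizeTrack(tk$run$tracks[[1]], out$frames, distance = 3)
    expect_identical(ncol(ft$profiles), 176L)
    expect_true(all(case$cmp(apply(ft$profiles, 1, max), 1.2)))
    ft2 <- featurizeTrack(tk$run$tracks[[1]], out$frames, distance = 3)
    expect_identical(ft$profiles, ft2$profiles)
  }
})

test_that("scaling in-mask heights scales every profile entry linearly", {
  set.seed(41)
  f <- matrix(0, 132, 176)
  f[40:90, ] <- runif(51 * 176, 0, 1.5)
  p1 <- backboneProfile(gaussianSmooth(f, 1))
  p2 <- backboneProfile(gaussianSmooth(2.5 * f, 1))
  expect_equal(p2, 2.5 * p1, tolerance = 1e-9)
})
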