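# Stain normalization, classifier architecture, classification augmentation.

test_that("Reinhard normalization is the identity on its own target and
           idempotent", {
  set.seed(2)
  img <- array(runif(30 * 30 * 3, 0.1, 0.9), c(30, 30, 3))
  self <- stainTarget(img)
  expect_lt(max(abs(reinhardNormalize(img, self) - img)), 1 / 255)
  other <- stainTarget(array(runif(300, 0.2, 0.8), c(10, 10, 3)))
  once <- reinhardNormalize(img, other)
  twice <- reinhardNormalize(once, other)
  expect_lt(max(abs(twice - once)), 2 / 255)
  # normalization contracts channel-statistic distance to the target
  statDist <- function(x, tg) {
    lab <- histoseg:::.toLab(x)
    sum(abs(colMeans(lab) - tg@mean)) +
      sum(abs(apply(lab, 2, stats::sd) - tg@sd))
  }
  expect_lt(statDist(once, other), statDist(img, other))
})

test_that("a constant-color image maps onto the target means", {
  img <- array(rep(c(0.7, 0.4, 0.6), each = 100), c(10, 10, 3))
  tgImg <- array(runif(300, 0.3, 0.8), c(10, 10, 3))
  tg <- stainTarget(tgImg)
  out <- reinhardNormalize(img, tg)
  labOut <- histoseg:::.toLab(out)
  # degenerate (zero-variance) channels are mean-shifted, not amplified
  expect_lt(max(abs(colMeans(labOut) - tg@mean)), 0.02)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("the l-alpha-beta transform matches a hand-computed pixel", {
  # one mid-gray pixel: LMS = M %*% rgb, channels log10-ed, then the
  # orthonormal Ruderman mixing
  rgb <- c(0.5, 0.5, 0.5)
  lms <- log10(pmax(histoseg:::.rgb2lms %*% rgb, 1e-4))
  expected <- c(sum(lms) / sqrt(3),
                (lms[1] + lms[2] - 2 * lms[3]) / sqrt(6),
                (lms[1] - lms[2]) / sqrt(2))
  got <- histoseg:::.toLab(array(rep(0.5, 3), c(1, 1, 3)))
  expect_equal(as.vector(got), expected, tolerance = 1e-12)
})

test_that("the patch classifier has exactly 32 weighted layers", {
  spec <- buildResNet32(3, width = 1 / 8)
  expect_identical(countWeightedLayers(spec), 32L)
  # stage plan is configurable but must keep 10 bottleneck units
  alt <- buildResNet32(3, width = 1 / 8, units = c(3L, 2L, 2L, 3L))
  expect_identical(countWeightedLayers(alt), 32L)
  # a same-width 50-layer build has strictly more parameters
  h <- asNamespace("histoseg")
  p32 <- parameterCount(h$initNetworkWeights(spec))
  b <- h$newGraphBuilder()
  x <- h$addNode(b, "conv", 0L, list(k = 3L, cin = 3L, cout = 8L,
                                     stride = 2L, pad = "same",
                                     groups = 1L), "c")
  cin <- 8L
  for (s in 1:4) {
    mid <- 8L * 2L^(s - 1L)
    for (u in seq_len(c(3L, 4L, 6L, 3L)[s])) {
      x <- h$addBottleneck(b, x, cin, mid, 4L * mid,
                           stride = if (u == 1L) 2L else 1L,
                           project = (u == 1L), part = "c")
      cin <- 4L * mid
    }
  }
  x <- h$addNode(b, "gap", x, list(), "c")
  x <- h$addNode(b, "dense", x, list(cin = cin, out = 3L), "c")
  spec50 <- h$finishGraph(b, "r50")
  expect_identical(countWeightedLayers(spec50), 50L)
  p50 <- parameterCount(h$initNetworkWeights(spec50))
  expect_lt(p32, p50)
})

test_that("classifier forward yields a probability 3-vector", {
  net <- randomNetwork(buildResNet32(3, width = 1 / 8), 1)
  x <- array(runif(224 * 224 * 3), c(224, 224, 3))
  p <- forwardNetwork(net, x)
  expect_identical(dim(p)[1:3], c(1L, 1L, 3L))
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1)
})

test_that("classification augmentation crops to 224 and permutes pixels", {
  set.seed(4)
  patch <- array(runif(256 * 256 * 3), c(256, 256, 3))
  out <- augmentCls(patch, seed = 1L)
  expect_identical(dim(out), c(224L, 224L, 3L))
  # corner crop with no flip/rotation reproduces the top-left window
  d0 <- list(r0 = 0L, c0 = 0L, flipV = FALSE, flipH = FALSE, rot90 = 0L)
  expect_identical(augmentCls(patch, draw = d0),
                   patch[1:224, 1:224, , drop = FALSE])
  # flips/rotations preserve the pixel multiset of the crop
  d1 <- list(r0 = 5L, c0 = 9L, flipV = TRUE, flipH = TRUE, rot90 = 3L)
  a <- augmentCls(patch, draw = d1)
  ref <- patch[5L + 1:224, 9L + 1:224, , drop = FALSE]
  expect_identical(sort(as.vector(a)), sort(as.vector(ref)))
  expect_error(augmentCls(array(0, c(128, 128, 3))), "256")
})

test_that("patch training selects the best epoch and predicts
           deterministically", {
  gen <- generateClassificationPatches(2L, 12L, seed = 8L, effect = 0.9,
                                       ndFraction = 0.4)
  labs <- vapply(gen$patches, `[[`, "", "label")
  # tiny smoke configuration
  cfg <- clsTrainConfig(width = 1 / 16, inputSide = 32L, epochs = 3L,
                        batchSize = 4L, lr = 1e-3)
  net <- trainPatchClassifier(gen$patches, config = cfg, seed = 2L)
  expect_length(net@history$valAccuracy, 3L)
  expect_true(net@history$selectedEpoch %in% 1:3)
  expect_identical(net@history$selectedEpoch,
                   which.max(net@history$valAccuracy))
  p1 <- predictPatch(net, gen$patches[[1]]$image)
  p2 <- predictPatch(net, gen$patches[[1]]$image)
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1)
  expect_named(p1, c("ND", "LUAD", "LUSC"))
  # seed-pinned rerun reproduces the selected epoch
  net2 <- trainPatchClassifier(gen$patches, config = cfg, seed = 2L)
  expect_identical(net2@history$selectedEpoch, net@history$selectedEpoch)
  expect_identical(net2@weights, net@weights)
  # missing class errors
  sub <- gen$patches[labs != "ND"]
  expect_error(trainPatchClassifier(sub, config = cfg, seed = 1L), "class")
})
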