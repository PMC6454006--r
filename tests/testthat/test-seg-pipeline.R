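# Post-processing: border subtraction, watershed separation, area filter,
# sliding-window stitching.

test_that("separateNuclei splits bordered fused objects and partitions the
           blob", {
  # two fused discs with a 1-px border line between them
  blob <- matrix(0, 30, 30); blob[10:20, 5:25] <- 1
  border <- matrix(0, 30, 30); border[10:20, 15] <- 1
  sep <- separateNuclei(blob, border)
  expect_identical(maskObjectCount(sep), 2L)
  # labels are a partition of the blob foreground
  expect_identical(sep > 0, blob > 0)
  # empty border: labels = connected components of the blob
  two <- matrix(0, 20, 20); two[2:6, 2:6] <- 1; two[12:18, 12:18] <- 1
  lab <- separateNuclei(two, matrix(0, 20, 20))
  expect_identical(maskObjectCount(lab), 2L)
  expect_identical(lab > 0, two > 0)
  # empty blob -> empty labeling
  expect_true(all(separateNuclei(matrix(0, 10, 10),
                                 matrix(0, 10, 10)) == 0L))
  expect_error(separateNuclei(blob, matrix(0, 5, 5)), "dimension")
})

test_that("a blob fully covered by dilated border keeps its detection", {
  blob <- matrix(0, 12, 12); blob[5:7, 5:7] <- 1
  border <- matrix(0, 12, 12); border[5:7, 5:7] <- 1
  sep <- separateNuclei(blob, border)
  expect_identical(maskObjectCount(sep), 1L)
  expect_identical(sep > 0, blob > 0)
})

test_that("separation never merges and never labels outside the blob", {
  set.seed(31)
  for (k in 1:6) {
    blob <- matrix(as.numeric(matrix(runif(400), 20) > 0.55), 20, 20)
    border <- matrix(as.numeric(matrix(runif(400), 20) > 0.85), 20, 20)
    sep <- separateNuclei(blob, border)
    expect_true(all(sep[blob == 0] == 0L))
    expect_identical(sep > 0, blob > 0)  # partition of the support
    expect_gte(maskObjectCount(sep), floodFillComponents(blob > 0, 8))
  }
})

test_that("geodesic assignment matches the Euclidean oracle on convex
           supports", {
  h <- asNamespace("histoseg")
  blob <- matrix(0, 24, 24); blob[4:21, 4:21] <- 1
  markers <- matrix(0L, 24, 24)
  markers[7, 7] <- 1L; markers[18, 16] <- 2L
  geo <- h$.geodesic_label(matrix(as.integer(blob), 24), markers)
  eu <- h$.euclideanNearestCore(blob, markers)
  # geodesic distance on a convex support approximates Euclidean; allow the
  # 8-connectivity metric's small boundary band to differ
  agree <- mean(geo[blob > 0] == eu[blob > 0])
  expect_gt(agree, 0.95)
  # marker cells always keep their own label
  expect_identical(geo[7, 7], 1L)
  expect_identical(geo[18, 16], 2L)
})

test_that("area filter converts 13 um^2 with mpp and keeps threshold ties", {
  lm <- matrix(0L, 40, 40)
  lm[1:10, 1:10] <- 1L       # 100 px
  lm[20:34, 20:39] <- 2L     # 300 px
  # mpp 0.25: pixel threshold 13 / 0.25^2 = 208
  f1 <- areaFilter(lm, 13, mpp = 0.25)
  expect_identical(sort(unique(as.vector(f1))), c(0L, 1L))
  expect_identical(sum(f1 == 1L), 300L)
  # mpp 0.5: threshold 52 px -> both survive, ids compacted in order
  f2 <- areaFilter(lm, 13, mpp = 0.5)
  expect_identical(sort(unique(as.vector(f2))), c(0L, 1L, 2L))
  # object exactly at the pixel threshold is kept
  ex <- matrix(0L, 60, 60); ex[1:13, 1:16] <- 1L  # 208 px
  expect_identical(maskObjectCount(areaFilter(ex, 13, 0.25)), 1L)
  ex2 <- matrix(0L, 60, 60); ex2[1:9, 1:23] <- 1L  # 207 px
  expect_identical(maskObjectCount(areaFilter(ex2, 13, 0.25)), 0L)
  expect_error(areaFilter(lm, 13, mpp = 0), "positive")
})

test_that("oracle-mask pipeline recovers every nucleus on synthetic tiles", {
  spec <- syntheticTileSpec(width = 340L, height = 340L, nNuclei = 8L,
                            radiusRange = c(12, 16), touchingFraction = 0.3,
                            seed = 21L)
  tile <- generateNucleiTile(spec)
  mask <- tileMask(tile)
  labels <- segmentTile(NULL, NULL, tile,
                        oracle = list(blob = mask > 0,
                                      border = makeBorderTarget(mask, 2L)))
  expect_identical(maskObjectCount(labels), 8L)
  expect_equal(dice1(mask, labels), 1)
  expect_gt(dice2(mask, labels), 0.97)
  # injected all-zero blob -> empty labeling
  z <- segmentTile(NULL, NULL, tile,
                   oracle = list(blob = matrix(0, 340, 340),
                                 border = matrix(0, 340, 340)))
  expect_true(all(z == 0L))
})

test_that("sliding-window stitching covers tiles of any size exactly", {
  spec <- buildDRAN(2, width = 1 / 32)
  net <- randomNetwork(spec, 4)
  for (side in c(54L, 80L, 108L)) {
    img <- array(runif(side * side * 3), c(side, side, 3))
    out <- predictMask(net, img)
    expect_identical(dim(out$prob), c(side, side))
    expect_true(all(out$prob >= 0 & out$prob <= 1))
    expect_identical(dim(out$mask), c(side, side))
  }
  # threshold is inclusive
  cfg <- inferenceConfig(blobThreshold = 0.5)
  p <- matrix(c(0.49, 0.5, 0.51, 0.2), 2)
  expect_identical(matrix(as.numeric(p >= cfg$blobThreshold), 2),
                   matrix(c(0, 1, 1, 0), 2))
})

test_that("labelConnected distinguishes 4- and 8-connectivity", {
  m <- matrix(0L, 4, 4)
  m[1, 1] <- 1L; m[2, 2] <- 1L  # diagonal touch
  expect_identical(max(labelConnected(m, 8L)), 1L)
  expect_identical(max(labelConnected(m, 4L)), 2L)
  # components agree with the flood-fill oracle on random masks
  set.seed(8)
  for (k in 1:5) {
    bin <- matrix(runif(150) > 0.6, 15, 10)
    expect_identical(max(labelConnected(bin, 8L)),
                     floodFillComponents(bin, 8))
    expect_identical(max(labelConnected(bin, 4L)),
                     floodFillComponents(bin, 4))
  }
})
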