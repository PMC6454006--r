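# Architecture and training-schedule contracts of the segmentation networks.

h <- asNamespace("histoseg")

test_that("contracting path follows the stated spatial/channel chains", {
  spec <- buildContractingPath(width = 1 / 32)
  sh <- propagateShapes(spec, c(102, 102, 3))
  # stem: 102 - 6 = 96 (valid 7x7 stride 1)
  expect_equal(unname(sh[1, 1:2]), c(96, 96))
  # stage spatial chain 96 -> 96 -> 48 -> 24 -> 12; channels x(1/32)
  sides <- sh[, 1]
  expect_true(all(c(96, 48, 24, 12) %in% sides))
  expect_equal(unname(sh[nrow(sh), 3]), 2048 / 32)
  # stage output channels 256/512/1024/2048 scaled
  expect_true(all((c(256, 512, 1024, 2048) / 32) %in% sh[, 3]))
})

test_that("DRAN maps 102x102 to 54x54 with the Table-1 decoder chain", {
  spec <- buildDRAN(2, width = 1 / 32)
  sh <- propagateShapes(spec, c(102, 102, 3))
  expect_equal(unname(sh[nrow(sh), ]), c(54, 54, 2))
  # every valid-padded decoder reduces each side by exactly 6 (4 + 2)
  kinds <- vapply(spec@layers, `[[`, "", "kind")
  for (i in which(kinds == "conv")) {
    p <- spec@layers[[i]]$params
    if (p$pad != "valid" || p$k != 5L) next
    j <- i + 6L  # conv5-bn-relu-gconv3-bn-relu-conv1 decoder block
    expect_identical(spec@layers[[j]]$kind, "conv")
    expect_equal(unname(sh[i - 1L, 1] - sh[j, 1]), 6)
  }
  # decoder1 emits 128-channel maps ahead of the classifier head (width-scaled)
  headIn <- spec@layers[[length(spec@layers) - 1L]]$params$cin
  expect_equal(headIn, 128 / 32)
  # per-pixel probabilities sum to 1
  net <- randomNetwork(spec, 2)
  y <- forwardNetwork(net, array(runif(102 * 102 * 3), c(102, 102, 3)))
  expect_identical(dim(y)[1:3], c(54L, 54L, 2L))
  expect_lt(max(abs(apply(y, c(1, 2, 4), sum) - 1)), 1e-9)
})

test_that("MDRAN fuses three branches into a 54x54 map via decoder4", {
  spec <- buildMDRAN(2, width = 1 / 32)
  sh <- propagateShapes(spec, c(102, 102, 3))
  expect_equal(unname(sh[nrow(sh), ]), c(54, 54, 2))
  # decoder4's first convolution consumes the width of ONE decoder1 output
  d4first <- NULL
  for (ly in spec@layers)
    if (ly$part == "decoder4" && ly$kind == "conv") { d4first <- ly; break }
  expect_equal(d4first$params$cin, 128 / 32)
  expect_equal(d4first$params$cout, 256 / 32)
  expect_identical(d4first$params$pad, "same")
  net <- randomNetwork(spec, 3)
  y <- forwardNetwork(net, array(runif(102 * 102 * 3), c(102, 102, 3)))
  expect_identical(dim(y)[1:3], c(54L, 54L, 2L))
})

test_that("branch weights transplant into the multiscale network", {
  sch <- dranSchedule(1L, 0L); sch$batchSize <- 2L
  tile <- squareNucleusTile(220L)
  patches <- extractNBL(tile, nRandom = 2L, seed = 1L)
  dran <- trainDRAN(patches, "blob", schedule = sch, seed = 1L,
                    width = 1 / 32, stepsPerEpoch = 1L)
  md <- mdranFromBranches(list("x0.5" = dran, x1 = dran, x2 = dran),
                          width = 1 / 32, seed = 2L)
  rng <- md@spec@meta$branches$x1
  src <- dran@spec@meta$body
  expect_identical(md@weights[[rng[1]]], dran@weights[[src[1]]])
  expect_identical(md@weights[[rng[2]]], dran@weights[[src[2]]])
  expect_error(mdranFromBranches(list(x1 = dran)), "x0.5")
})

test_that("learning-rate schedule reproduces the printed breakpoints", {
  sch <- dranSchedule()
  p1 <- sch$phases[[1]]
  expect_equal(scheduleLR(p1, 0), 1e-4)
  expect_equal(scheduleLR(p1, 1), 5e-5)
  expect_equal(scheduleLR(p1, 15), 1e-5)
  expect_equal(scheduleLR(p1, 16), 1e-5)  # holds between breakpoints
  expect_equal(scheduleLR(p1, 25), 7.5e-6)
  expect_equal(scheduleLR(sch$phases[[2]], 0), 5e-6)
  expect_identical(p1$epochs, 35L)
  expect_identical(sch$phases[[2]]$epochs, 40L)
  expect_identical(sch$batchSize, 32L)
  expect_equal(sch$l2, 1e-5)
  msch <- mdranSchedule()
  expect_identical(msch$phases[[1]]$trainable, "decoder4")
  expect_equal(scheduleLR(msch$phases[[2]], 15), 1e-5)
  expect_equal(scheduleLR(msch$phases[[2]], 30), 1e-6)
})

test_that("a 2-epoch smoke run records losses and learning rates", {
  tile <- squareNucleusTile(220L)
  patches <- extractNBL(tile, nRandom = 4L, seed = 2L)
  sch <- dranSchedule(2L, 0L); sch$batchSize <- 4L
  net <- trainDRAN(patches, "border", schedule = sch, seed = 3L,
                   width = 1 / 32, stepsPerEpoch = 2L)
  expect_length(net@history$loss, 2L)
  expect_equal(net@history$lr, c(1e-4, 5e-5))
  expect_true(all(is.finite(net@history$loss)))
  expect_error(trainDRAN(list(), "blob"), "empty")
})

test_that("MDRAN phases freeze exactly the stated parameter groups", {
  tile <- squareNucleusTile(220L)
  patches <- extractNBL(tile, nRandom = 2L, seed = 4L)
  sch <- dranSchedule(1L, 0L); sch$batchSize <- 2L
  dran <- trainDRAN(patches, "blob", schedule = sch, seed = 5L,
                    width = 1 / 32, stepsPerEpoch = 1L)
  branches <- list("x0.5" = dran, x1 = dran, x2 = dran)
  parts <- function(net) vapply(net@spec@layers, `[[`, "", "part")

  # phase A only: branch weights bit-identical to the assembled start
  mstart <- mdranFromBranches(branches, width = 1 / 32, seed = 6L)
  schA <- mdranSchedule(1L, 0L); schA$batchSize <- 2L
  mA <- trainMDRAN(branches, patches, "blob", schedule = schA, seed = 6L,
                   width = 1 / 32, stepsPerEpoch = 1L)
  pt <- parts(mA)
  for (i in which(pt %in% c("contracting", "expanding")))
    expect_identical(mA@weights[[i]], mstart@weights[[i]])
  changedD4 <- any(vapply(which(pt == "decoder4"), function(i)
    !identical(mA@weights[[i]], mstart@weights[[i]]), TRUE))
  expect_true(changedD4)

  # phase B: expanding paths move, contracting stays frozen
  schB <- mdranSchedule(0L, 1L); schB$batchSize <- 2L
  mB <- trainMDRAN(branches, patches, "blob", schedule = schB, seed = 6L,
                   width = 1 / 32, stepsPerEpoch = 1L)
  for (i in which(pt == "contracting"))
    expect_identical(mB@weights[[i]], mstart@weights[[i]])
  changedExp <- any(vapply(which(pt == "expanding"), function(i)
    !identical(mB@weights[[i]], mstart@weights[[i]]), TRUE))
  expect_true(changedExp)
})
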