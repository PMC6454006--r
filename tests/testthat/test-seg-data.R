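test_that("NBL extraction counts follow the sliding/random geometry", {
  tileA <- squareNucleusTile(200L)
  pa <- extractNBL(tileA, step = 54L, nRandom = 30L, seed = 1L)
  expect_length(pa, 31L)  # 1 sliding position + 30 random
  tileB <- squareNucleusTile(308L)
  pb <- extractNBL(tileB, step = 54L, nRandom = 30L, seed = 1L)
  expect_length(pb, 39L)  # 3 x 3 sliding + 30 random
  expect_true(all(vapply(pb, function(p)
    identical(dim(p$image), c(200L, 200L, 3L)), TRUE)))
  # determinism and per-tile substream: same content regardless of other work
  pb2 <- extractNBL(tileB, step = 54L, nRandom = 30L, seed = 1L)
  expect_identical(pb, pb2)
  expect_error(extractNBL(NucleiTile(array(0.5, c(150, 150, 3)),
                                     matrix(0L, 150, 150))),
               "smaller")
})

test_that("NBD patches center each interior nucleus and skip edge nuclei", {
  side <- 320L
  mask <- matrix(0L, side, side)
  # one interior nucleus centered at (160,160) in 1-based coords
  mask[156:165, 156:165] <- 1L
  # an edge-adjacent nucleus (centroid < 100 px from the top edge)
  mask[40:49, 156:165] <- 2L
  img <- array(0.8, c(side, side, 3))
  tile <- NucleiTile(img, mask, id = "nbd")
  ps <- extractNBD(tile)
  expect_length(ps, 1L)
  # centroid lands on the patch center cell (0-based (100, 100))
  expect_equal(ps[[1]]$tag, "NBD")
  blob <- ps[[1]]$blob
  expect_equal(blob[101, 101], 1)
  ctr <- which(blob > 0, arr.ind = TRUE)
  expect_equal(floor(mean(ctr[, 1] - 1)), 100)
  expect_equal(floor(mean(ctr[, 2] - 1)), 100)
  # empty mask -> empty list; missing mask -> error
  expect_length(extractNBD(NucleiTile(img, matrix(0L, side, side))), 0L)
  expect_error(extractNBD(NucleiTile(img)), "mask")
})

test_that("SN duplication keeps sparse-center patches exactly 3 times", {
  mkPatch <- function(frac) {
    blob <- matrix(0, 200, 200)
    nOn <- round(frac * 54 * 54)
    win <- matrix(0, 54, 54)
    win[seq_len(nOn)] <- 1
    blob[74:127, 74:127] <- win
    list(image = array(0.5, c(200, 200, 3)), blob = blob,
         border = matrix(0, 200, 200), tag = "NBL", tile = "t",
         offset = c(0L, 0L))
  }
  sn <- extractSN(list(mkPatch(0.3), mkPatch(0.6), mkPatch(0.5)))
  # 30% qualifies, 60% excluded, exactly 50% inclusive
  expect_length(sn, 6L)
  expect_true(all(vapply(sn, `[[`, "", "tag") == "SN"))
  # SN image is byte-identical to its source
  expect_identical(sn[[1]]$image, mkPatch(0.3)$image)
})

test_that("border targets thicken object outlines and shared interfaces", {
  m <- matrix(0L, 14, 14); m[3:12, 3:12] <- 1L
  b <- makeBorderTarget(m, thickness = 2L)
  expect_equal(sum(b), 64)            # 10x10 square: outer 2-pixel ring
  expect_true(all(m[b > 0] > 0))      # border lies inside the foreground
  expect_equal(sum(makeBorderTarget(matrix(0L, 10, 10))), 0)
  # two touching objects: the shared interface is border on both sides
  t2 <- matrix(0L, 12, 20)
  t2[3:10, 3:10] <- 1L; t2[3:10, 11:18] <- 2L
  bt <- makeBorderTarget(t2, thickness = 1L)
  expect_true(all(bt[3:10, 10] == 1))
  expect_true(all(bt[3:10, 11] == 1))
  # thickness-1 border is the exact outline set
  m1 <- makeBorderTarget(m, thickness = 1L)
  expect_equal(sum(m1), 36)
})

test_that("augmentation transforms image and targets jointly", {
  tile <- squareNucleusTile(240L)
  p <- extractNBL(tile, nRandom = 0L, seed = 1L)[[1]]
  idDraw <- list(shift = c(0, 0), rotation = 0, flipV = FALSE,
                 flipH = FALSE, shear = 0, scale = 1)
  same <- augmentPatch(p, draw = idDraw)
  expect_equal(same$image, p$image)
  expect_equal(same$blob, p$blob)
  # horizontal flip reverses columns of image and targets alike
  fl <- augmentPatch(p, draw = modifyList(idDraw, list(flipH = TRUE)))
  expect_equal(fl$image, p$image[, 200:1, , drop = FALSE],
               ignore_attr = TRUE)
  expect_equal(fl$blob, p$blob[, 200:1])
  # flipping twice is the identity
  fl2 <- augmentPatch(fl, draw = modifyList(idDraw, list(flipH = TRUE)))
  expect_equal(fl2$image, p$image)
  # arbitrary draws keep targets binary and sizes fixed
  set.seed(9)
  for (k in 1:5) {
    a <- augmentPatch(p, augmentParams())
    expect_identical(dim(a$image), c(200L, 200L, 3L))
    expect_true(all(a$blob %in% c(0, 1)))
    expect_true(all(a$border %in% c(0, 1)))
  }
  # dataset-level build is deterministic and 3x the input size
  aug <- augmentDataset(list(p), augmentParams(), seed = 3L)
  aug2 <- augmentDataset(list(p), augmentParams(), seed = 3L)
  expect_length(aug, 3L)
  expect_identical(aug, aug2)
})

test_that("center and target crops use the floor-centered offset", {
  x <- array(seq_len(200 * 200 * 3), c(200, 200, 3))
  cc <- centerCrop(x, 102L)
  expect_identical(dim(cc), c(102L, 102L, 3L))
  expect_equal(cc[1, 1, 1], x[50, 50, 1])  # offset (49, 49) 0-based
  tc <- targetCrop(x, 54L)
  expect_equal(tc[1, 1, 1], x[74, 74, 1])  # offset (73, 73) 0-based
  # target crop aligns with the center of the 102 input
  expect_equal(centerCrop(cc, 54L), tc)
  # crop of a crop equals crop at the combined offset
  expect_equal(centerCrop(centerCrop(x, 150L), 102L), centerCrop(x, 102L))
  expect_error(centerCrop(array(0, c(50, 50, 3)), 102L), "smaller")
})
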