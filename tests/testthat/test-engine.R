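# The network engine: shape propagation, gradients, parameter accounting.

h <- asNamespace("histoseg")

.tinyClassNet <- function() {
  b <- h$newGraphBuilder()
  x <- h$addNode(b, "conv", 0L, list(k = 3L, cin = 2L, cout = 4L,
                                     stride = 1L, pad = "same",
                                     groups = 2L), "a")
  x <- h$addNode(b, "bn", x, list(cin = 4L), "a")
  x <- h$addNode(b, "relu", x, list(), "a")
  x <- h$addNode(b, "tconv", x, list(cin = 4L, cout = 3L), "a")
  x <- h$addNode(b, "conv", x, list(k = 5L, cin = 3L, cout = 2L,
                                    stride = 2L, pad = "valid",
                                    groups = 1L), "b")
  x <- h$addNode(b, "gap", x, list(), "b")
  x <- h$addNode(b, "dense", x, list(cin = 2L, out = 3L), "b")
  x <- h$addNode(b, "softmax", x, list(), "b")
  h$finishGraph(b, "tiny")
}

test_that("symbolic shapes match observed forward shapes on random sizes", {
  spec <- buildDRAN(2, width = 1 / 32)
  net <- randomNetwork(spec, 1)
  set.seed(3)
  # valid DRAN inputs: the encoder/decoder side chain closes only when the
  # post-stem side is a multiple of 8 (side = 8k + 6), as for 102
  for (side in 6L + 8L * sample(10:17, 4L)) {
    sh <- propagateShapes(spec, c(side, side, 3))
    out <- forwardNetwork(net, array(0.5, c(side, side, 3)))
    expect_identical(dim(out)[1:3], as.integer(sh[nrow(sh), ]),
                     info = paste("side", side))
  }
})

test_that("analytic gradients match finite differences", {
  spec <- .tinyClassNet()
  set.seed(7)
  w <- h$initNetworkWeights(spec, 7)
  x <- array(rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3))
  lab <- c(1L, 3L, 2L)
  lossOf <- function(w)
    h$classCrossEntropy(h$netForward(spec, w, x, TRUE)$out, lab)$loss
  fw <- h$netForward(spec, w, x, TRUE)
  gr <- h$netBackward(spec, w, fw, h$classCrossEntropy(fw$out, lab)$grad)
  for (ni in seq_along(gr)) {
    g <- gr[[ni]]
    if (is.null(g)) next
    for (nm in names(g)) {
      arr <- w[[ni]][[nm]]
      for (k in sample(seq_along(arr), min(4L, length(arr)))) {
        wp <- w; wp[[ni]][[nm]][k] <- arr[k] + 1e-5
        wm <- w; wm[[ni]][[nm]][k] <- arr[k] - 1e-5
        num <- (lossOf(wp) - lossOf(wm)) / 2e-5
        expect_lt(abs(num - g[[nm]][k]) /
                    max(1e-4, abs(num) + abs(g[[nm]][k])), 1e-5)
      }
    }
  }
})

test_that("frozen parts receive no gradients but grads still flow through", {
  spec <- .tinyClassNet()
  w <- h$initNetworkWeights(spec, 1)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2, 1))
  fw <- h$netForward(spec, w, x, TRUE)
  gr <- h$netBackward(spec, w, fw,
                      h$classCrossEntropy(fw$out, 2L)$grad,
                      trainable = "a")
  parts <- vapply(spec@layers, `[[`, "", "part")
  hasW <- !vapply(w, is.null, TRUE)
  expect_true(all(vapply(which(parts == "b" & hasW),
                         function(i) is.null(gr[[i]]), TRUE)))
  expect_true(any(vapply(which(parts == "a" & hasW),
                         function(i) !is.null(gr[[i]]), TRUE)))
})

test_that("grouped convolutions carry 1/groups of the ungrouped parameters", {
  mk <- function(groups) {
    b <- h$newGraphBuilder()
    h$addNode(b, "conv", 0L, list(k = 3L, cin = 16L, cout = 32L,
                                  stride = 1L, pad = "same",
                                  groups = groups), "a")
    h$initNetworkWeights(h$finishGraph(b, "g"), 1)
  }
  nG <- length(mk(4L)[[1]]$W)
  n1 <- length(mk(1L)[[1]]$W)
  expect_identical(n1, 3L * 3L * 16L * 32L)
  expect_identical(nG * 4L, n1)
  # analytic formula: k^2 * cin/g * cout
  expect_identical(nG, 3L * 3L * 4L * 32L)
})

test_that("weighted loss reproduces the stated per-pixel penalties", {
  mk <- function(pfg) {
    p <- array(0, c(1, 1, 2, 1))
    p[1, 1, 1, 1] <- 1 - pfg
    p[1, 1, 2, 1] <- pfg
    p
  }
  # border pixel, p = 0.5 (tie -> predicted background): 6 * ln 2
  expect_equal(weightedLoss(mk(0.5), matrix(1, 1, 1))$loss, 6 * log(2),
               tolerance = 1e-12)
  # border pixel predicted border: 5 * -ln p
  expect_equal(weightedLoss(mk(0.6), matrix(1, 1, 1))$loss, 5 * -log(0.6),
               tolerance = 1e-12)
  expect_equal(round(weightedLoss(mk(0.5 + 1e-12),
                                  matrix(1, 1, 1))$loss, 3), 3.466)
  # correct background pixel with certainty: zero loss
  expect_equal(weightedLoss(mk(0), matrix(0, 1, 1))$loss, 0)
  # background pixel predicted border: 4 * -ln(1 - p)
  expect_equal(weightedLoss(mk(0.7), matrix(0, 1, 1))$loss, 4 * -log(0.3),
               tolerance = 1e-12)
  # clamped pixels are counted
  expect_identical(weightedLoss(mk(0), matrix(1, 1, 1))$n_clamped, 1L)
})

test_that("L2 factor zero leaves the loss unregularized exactly", {
  spec <- .tinyClassNet()
  w <- h$initNetworkWeights(spec, 2)
  pen <- h$l2Penalty(w)
  expect_gt(pen, 0)
  base <- 0.5
  expect_identical(base + 0 * pen, base)
  # Adam with l2 = 0 uses the bare gradient
  g <- list(list(W = array(1, c(1, 1, 1, 1)), b = 0))
  w1 <- list(list(W = array(2, c(1, 1, 1, 1)), b = 0))
  s0 <- h$adamInit()
  up0 <- h$adamStep(w1, g, s0, lr = 0.1, l2 = 0)
  up1 <- h$adamStep(w1, g, h$adamInit(), lr = 0.1, l2 = 0.5)
  expect_false(identical(up0$weights[[1]]$W, up1$weights[[1]]$W))
})

test_that("networks forward deterministically for fixed weights", {
  spec <- .tinyClassNet()
  net <- randomNetwork(spec, 5)
  x <- array(runif(6 * 6 * 2), c(6, 6, 2))
  expect_identical(forwardNetwork(net, x), forwardNetwork(net, x))
})
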