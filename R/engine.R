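#' @include AllClasses.R utils.R
NULL

# ---------------------------------------------------------------------------
# Layer-graph construction. A builder is an environment accumulating layer
# nodes; each node: list(id, kind, inputs, params, part). Input id 0 refers to
# the network input. Nodes are added in topological order by construction.
# ---------------------------------------------------------------------------

newGraphBuilder <- function() {
  b <- new.env(parent = emptyenv())
  b$layers <- list()
  b
}

addNode <- function(b, kind, inputs, params = list(), part = "") {
  id <- length(b$layers) + 1L
  b$layers[[id]] <- list(id = id, kind = kind, inputs = as.integer(inputs),
                         params = params, part = part)
  id
}

finishGraph <- function(b, name, inputShape = c(NA_real_, NA_real_, 3),
                        meta = list()) {
  new("NetworkSpec", layers = b$layers, name = name,
      inputShape = as.numeric(inputShape), meta = meta)
}

convOutSide <- function(n, k, stride, pad) {
  if (pad == "valid") floor((n - k) / stride) + 1 else ceiling(n / stride)
}

convPadBefore <- function(n, k, stride, pad) {
  if (pad == "valid") return(0L)
  o <- ceiling(n / stride)
  as.integer(max((o - 1) * stride + k - n, 0) %/% 2)
}

#' Propagate tensor shapes through a network
#'
#' Symbolically computes the \code{(H, W, C)} output shape of every node for a
#' given input shape, checking that addition merges receive operands of
#' identical shape. This is the structural oracle the forward pass is tested
#' against.
#'
#' @param spec a \code{\link{NetworkSpec}}.
#' @param inputShape numeric \code{c(H, W, C)}.
#' @return matrix with one row per node and columns H, W, C.
#' @export
propagateShapes <- function(spec, inputShape) {
  L <- length(spec@layers)
  sh <- matrix(NA_real_, L, 3, dimnames = list(NULL, c("H", "W", "C")))
  getShape <- function(i) if (i == 0L) inputShape else sh[i, ]
  for (i in seq_len(L)) {
    ly <- spec@layers[[i]]
    p <- ly$params
    ins <- lapply(ly$inputs, getShape)
    s <- ins[[1]]
    sh[i, ] <- switch(ly$kind,
      conv = c(convOutSide(s[1], p$k, p$stride, p$pad),
               convOutSide(s[2], p$k, p$stride, p$pad), p$cout),
      tconv = c(2 * s[1], 2 * s[2], p$cout),
      bn = , relu = , softmax = s,
      add = {
        for (o in ins[-1]) if (!all(o == s))
          stop("shape mismatch at add node ", i, ": ",
               paste(s, collapse = "x"), " vs ",
               paste(o, collapse = "x"))
        s
      },
      resize = c(round(s[1] * p$factor), round(s[2] * p$factor), s[3]),
      resize_like = c(ins[[2]][1], ins[[2]][2], s[3]),
      crop_like = {
        r <- ins[[2]]
        if (r[1] > s[1] || r[2] > s[2])
          stop("crop_like target larger than source at node ", i)
        c(r[1], r[2], s[3])
      },
      crop = c(p$side, p$side, s[3]),
      gap = c(1, 1, s[3]),
      dense = c(1, 1, p$out),
      stop("unknown layer kind: ", ly$kind)
    )
    if (any(sh[i, 1:2] < 1))
      stop("non-positive spatial size at node ", i, " (", ly$kind, ")")
  }
  sh
}

#' Count weighted layers of a network
#'
#' Counts convolution, transpose-convolution and fully-connected layers,
#' excluding shortcut projection convolutions, following the ResNet naming
#' convention (ResNet50 = 50 such layers).
#'
#' @param spec a \code{\link{NetworkSpec}}.
#' @return integer layer count.
#' @export
countWeightedLayers <- function(spec) {
  sum(vapply(spec@layers, function(ly) {
    ly$kind %in% c("conv", "tconv", "dense") &&
      !identical(ly$params$role, "projection")
  }, logical(1)))
}

#' Total trainable parameter count
#'
#' @param x a \code{\link{TrainedNetwork}} or a weight list.
#' @return number of trainable parameters (kernels, biases, batch-norm scale
#'   and shift; running statistics excluded).
#' @export
parameterCount <- function(x) {
  w <- if (is(x, "TrainedNetwork")) x@weights else x
  tot <- 0
  for (nw in w) {
    if (is.null(nw)) next
    for (nm in intersect(names(nw), c("W", "b", "gamma", "beta")))
      tot <- tot + length(nw[[nm]])
  }
  tot
}

# He (fan-in) initialization of all weights of a spec.
initNetworkWeights <- function(spec, seed = NULL) {
  withSeed(seed, {
    lapply(spec@layers, function(ly) {
      p <- ly$params
      switch(ly$kind,
        conv = {
          cig <- p$cin / p$groups
          sd <- sqrt(2 / (p$k * p$k * cig))
          list(W = array(rnorm(p$k * p$k * cig * p$cout, sd = sd),
                         dim = c(p$k, p$k, cig, p$cout)),
               b = numeric(p$cout))
        },
        tconv = list(
          W = array(rnorm(4 * p$cin * p$cout, sd = sqrt(2 / p$cin)),
                    dim = c(2, 2, p$cin, p$cout)),
          b = numeric(p$cout)),
        bn = list(gamma = rep(1, p$cin), beta = numeric(p$cin),
                  rmean = numeric(p$cin), rvar = rep(1, p$cin)),
        dense = list(W = matrix(rnorm(p$out * p$cin, sd = sqrt(2 / p$cin)),
                                p$out, p$cin),
                     b = numeric(p$out)),
        NULL)
    })
  })
}

# Broadcast a per-channel vector over an (H, W, C, N) array's layout.
# Returns a length H*W*C vector; arithmetic recycles it across the batch.
.bcastC <- function(v, d) rep(v, each = d[1] * d[2])

# (H,W,C,N) array <-> (H*W*N) x C matrix, for per-channel operations.
.chanMat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}
.chanArr <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

.as4d <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 3-d or 4-d array")
  x
}

.bnEps <- 1e-5

# Forward pass. Returns list(out, outs, caches, batchStats) — outs/caches are
# kept only when training = TRUE (needed by the backward pass); in eval mode
# intermediate maps are freed as soon as all consumers have run.
netForward <- function(spec, weights, x, training = FALSE) {
  x <- .as4d(x)
  L <- length(spec@layers)
  outs <- vector("list", L)
  caches <- if (training) vector("list", L) else NULL
  batchStats <- if (training) vector("list", L) else NULL
  refcount <- integer(L)
  for (ly in spec@layers)
    for (j in ly$inputs) if (j > 0L) refcount[j] <- refcount[j] + 1L
  getIn <- function(i) if (i == 0L) x else outs[[i]]
  for (i in seq_len(L)) {
    ly <- spec@layers[[i]]
    p <- ly$params
    w <- weights[[i]]
    a <- getIn(ly$inputs[1])
    d <- dim(a)
    y <- switch(ly$kind,
      conv = {
        oh <- convOutSide(d[1], p$k, p$stride, p$pad)
        ow <- convOutSide(d[2], p$k, p$stride, p$pad)
        .conv_fwd(a, w$W, w$b, p$stride,
                  convPadBefore(d[1], p$k, p$stride, p$pad),
                  convPadBefore(d[2], p$k, p$stride, p$pad),
                  oh, ow, p$groups)
      },
      tconv = .tconv_fwd(a, w$W, w$b),
      bn = {
        if (training) {
          m2 <- matrix(a, d[1] * d[2], d[3] * d[4])
          cs <- colMeans(m2)
          mu <- rowMeans(matrix(cs, d[3], d[4]))
          va <- rowMeans(matrix(colMeans(m2^2), d[3], d[4])) - mu^2
          batchStats[[i]] <- list(mean = mu, var = va)
        } else {
          mu <- w$rmean
          va <- w$rvar
        }
        inv <- 1 / sqrt(va + .bnEps)
        xhat <- (a - .bcastC(mu, d)) * .bcastC(inv, d)
        if (training) caches[[i]] <- list(xhat = xhat, inv = inv)
        xhat * .bcastC(w$gamma, d) + .bcastC(w$beta, d)
      },
      relu = pmax(a, 0),
      add = {
        acc <- a
        for (j in ly$inputs[-1]) acc <- acc + getIn(j)
        acc
      },
      resize = {
        oh <- round(d[1] * p$factor); ow <- round(d[2] * p$factor)
        if (identical(p$mode, "bilinear")) .resize_bl_fwd(a, oh, ow)
        else .resize_nn_fwd(a, oh, ow)
      },
      resize_like = {
        r <- dim(getIn(ly$inputs[2]))
        if (identical(p$mode, "bilinear")) .resize_bl_fwd(a, r[1], r[2])
        else .resize_nn_fwd(a, r[1], r[2])
      },
      crop_like = {
        r <- dim(getIn(ly$inputs[2]))
        r0 <- (d[1] - r[1]) %/% 2
        c0 <- (d[2] - r[2]) %/% 2
        a[r0 + seq_len(r[1]), c0 + seq_len(r[2]), , , drop = FALSE]
      },
      crop = {
        r0 <- (d[1] - p$side) %/% 2
        c0 <- (d[2] - p$side) %/% 2
        a[r0 + seq_len(p$side), c0 + seq_len(p$side), , , drop = FALSE]
      },
      softmax = {
        m <- .chanMat(a)
        m <- exp(m - apply(m, 1, max))
        .chanArr(m / rowSums(m), d)
      },
      gap = {
        cm <- colMeans(matrix(a, d[1] * d[2], d[3] * d[4]))
        array(cm, c(1, 1, d[3], d[4]))
      },
      dense = {
        xm <- matrix(a, d[3], d[4])
        ym <- w$W %*% xm + w$b
        array(ym, c(1, 1, p$out, d[4]))
      },
      stop("unknown layer kind: ", ly$kind)
    )
    outs[[i]] <- y
    if (!training) {
      for (j in ly$inputs) if (j > 0L) {
        refcount[j] <- refcount[j] - 1L
        if (refcount[j] == 0L && j != L) outs[j] <- list(NULL)
      }
    }
  }
  list(out = outs[[L]], outs = if (training) outs, caches = caches,
       batchStats = batchStats, input = if (training) x)
}

# Backward pass. fw is the result of netForward(training = TRUE); dOut is the
# loss gradient w.r.t. the final node's output. trainable = parts whose weight
# gradients are needed (NULL = all). Returns list of per-node gradient lists.
netBackward <- function(spec, weights, fw, dOut, trainable = NULL) {
  L <- length(spec@layers)
  isTrain <- vapply(spec@layers, function(ly) {
    !is.null(weights[[ly$id]]) &&
      (is.null(trainable) || ly$part %in% trainable)
  }, logical(1))
  needs <- logical(L + 1L)  # index i+1 = node i; index 1 = network input
  for (i in seq_len(L)) {
    ly <- spec@layers[[i]]
    needs[i + 1L] <- isTrain[i] || any(needs[ly$inputs + 1L])
  }
  dnode <- vector("list", L)
  grads <- vector("list", L)
  dnode[[L]] <- dOut
  getIn <- function(i) if (i == 0L) fw$input else fw$outs[[i]]
  addGrad <- function(j, g) {
    if (j == 0L || !needs[j + 1L]) return(invisible())
    dnode[[j]] <<- if (is.null(dnode[[j]])) g else dnode[[j]] + g
  }
  for (i in rev(seq_len(L))) {
    d <- dnode[[i]]
    if (is.null(d) || !needs[i + 1L]) next
    ly <- spec@layers[[i]]
    p <- ly$params
    w <- weights[[i]]
    a <- getIn(ly$inputs[1])
    da <- dim(a)
    switch(ly$kind,
      conv = {
        bw <- .conv_bwd(a, w$W, d, p$stride,
                        convPadBefore(da[1], p$k, p$stride, p$pad),
                        convPadBefore(da[2], p$k, p$stride, p$pad),
                        p$groups)
        if (isTrain[i]) grads[[i]] <- list(W = bw$dw, b = bw$db)
        addGrad(ly$inputs[1], bw$dx)
      },
      tconv = {
        bw <- .tconv_bwd(a, w$W, d)
        if (isTrain[i]) grads[[i]] <- list(W = bw$dw, b = bw$db)
        addGrad(ly$inputs[1], bw$dx)
      },
      bn = {
        cch <- fw$caches[[i]]
        xhat <- cch$xhat
        m <- da[1] * da[2] * da[4]
        perC <- function(z)
          rowMeans(matrix(colSums(matrix(z, da[1] * da[2], da[3] * da[4])),
                          da[3], da[4])) * da[4] / m  # channel means
        dgamma <- perC(d * xhat) * m
        dbeta <- perC(d) * m
        if (isTrain[i]) grads[[i]] <- list(gamma = dgamma, beta = dbeta)
        dxhat <- d * .bcastC(w$gamma, da)
        dxm <- (dxhat - .bcastC(perC(dxhat), da) -
                  xhat * .bcastC(perC(dxhat * xhat), da)) *
          .bcastC(cch$inv, da)
        addGrad(ly$inputs[1], dxm)
      },
      relu = addGrad(ly$inputs[1], d * (a > 0)),
      add = for (j in ly$inputs) addGrad(j, d),
      resize = {
        if (identical(p$mode, "bilinear"))
          addGrad(ly$inputs[1], .resize_bl_bwd(d, da[1], da[2]))
        else addGrad(ly$inputs[1], .resize_nn_bwd(d, da[1], da[2]))
      },
      resize_like = {
        if (identical(p$mode, "bilinear"))
          addGrad(ly$inputs[1], .resize_bl_bwd(d, da[1], da[2]))
        else addGrad(ly$inputs[1], .resize_nn_bwd(d, da[1], da[2]))
      },
      crop_like = {
        dd <- dim(d)
        dx <- array(0, da)
        r0 <- (da[1] - dd[1]) %/% 2
        c0 <- (da[2] - dd[2]) %/% 2
        dx[r0 + seq_len(dd[1]), c0 + seq_len(dd[2]), , ] <- d
        addGrad(ly$inputs[1], dx)
      },
      crop = {
        dx <- array(0, da)
        r0 <- (da[1] - p$side) %/% 2
        c0 <- (da[2] - p$side) %/% 2
        dx[r0 + seq_len(p$side), c0 + seq_len(p$side), , ] <- d
        addGrad(ly$inputs[1], dx)
      },
      softmax = {
        pm <- .chanMat(fw$outs[[i]])
        dm <- .chanMat(d)
        dxm <- pm * (dm - rowSums(dm * pm))
        addGrad(ly$inputs[1], .chanArr(dxm, da))
      },
      gap = {
        g <- array(rep(as.vector(d) / (da[1] * da[2]),
                       each = da[1] * da[2]), da)
        addGrad(ly$inputs[1], g)
      },
      dense = {
        dm <- matrix(d, dim(d)[3], dim(d)[4])
        xm <- matrix(a, da[3], da[4])
        if (isTrain[i])
          grads[[i]] <- list(W = dm %*% t(xm), b = rowSums(dm))
        addGrad(ly$inputs[1], array(t(w$W) %*% dm, da))
      },
      stop("no backward for layer kind: ", ly$kind)
    )
    dnode[i] <- list(NULL)
  }
  grads
}

# ---------------------------------------------------------------------------
# Optimization
# ---------------------------------------------------------------------------

adamInit <- function() list(t = 0L, m = list(), v = list())

# One Adam step (beta1 = 0.9, beta2 = 0.999, eps = 1e-8). l2 is the L2
# regularization factor applied to conv/dense kernels (gradient 2 * l2 * W);
# with l2 = 0 the update uses the bare loss gradient.
adamStep <- function(weights, grads, state, lr, l2 = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      key <- paste0(i, ".", nm)
      gr <- g[[nm]]
      if (nm == "W" && l2 > 0) gr <- gr + 2 * l2 * weights[[i]][[nm]]
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- gr * 0
        state$v[[key]] <- gr * 0
      }
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * gr
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * gr^2
      weights[[i]][[nm]] <- weights[[i]][[nm]] -
        lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
    }
  }
  list(weights = weights, state = state)
}

# Update batch-norm running statistics from the batch statistics of a
# training forward pass (exponential moving average). `nodes` restricts the
# update to specific node ids (frozen parts keep their statistics).
updateRunningStats <- function(weights, batchStats, momentum = 0.1,
                               nodes = NULL) {
  for (i in seq_along(batchStats)) {
    bs <- batchStats[[i]]
    if (is.null(bs)) next
    if (!is.null(nodes) && !(i %in% nodes)) next
    weights[[i]]$rmean <- (1 - momentum) * weights[[i]]$rmean +
      momentum * bs$mean
    weights[[i]]$rvar <- (1 - momentum) * weights[[i]]$rvar +
      momentum * bs$var
  }
  weights
}

# Sum of squared conv/dense kernels (the L2 regularization term before the
# factor is applied).
l2Penalty <- function(weights) {
  s <- 0
  for (nw in weights) if (!is.null(nw$W)) s <- s + sum(nw$W^2)
  s
}

# ---------------------------------------------------------------------------
# Losses
# ---------------------------------------------------------------------------

#' Class-weighted segmentation cross-entropy
#'
#' Mean over pixels of \code{w(t, c) * (-log p_t)} where \code{t} is the true
#' class, \code{c} the predicted class (foreground iff its probability exceeds
#' 0.5; at an exact tie background is taken), and the weight table is 5.0 for
#' a correctly predicted foreground/border pixel, 6.0 for a border pixel
#' predicted background, 1.0 for a correct background pixel and 4.0 for a
#' background pixel predicted border. Probabilities below \code{eps} are
#' clamped before the logarithm.
#'
#' @param probs array \code{(H, W, 2, N)} of class probabilities
#'   (channel 1 = background, channel 2 = foreground/border).
#' @param target array \code{(H, W, N)} (or matrix) with entries 0/1.
#' @param weights numeric length 4: \code{c(fg, fg_miss, bg, bg_miss)}.
#' @param eps clamp for log; clamped pixels are counted in the returned
#'   \code{n_clamped}.
#' @return list with \code{loss} (scalar), \code{grad} (same shape as
#'   \code{probs}; gradient w.r.t. the probabilities) and \code{n_clamped}.
#' @export
weightedLoss <- function(probs, target,
                         weights = c(fg = 5, fg_miss = 6, bg = 1, bg_miss = 4),
                         eps = 1e-7) {
  probs <- .as4d(probs)
  d <- dim(probs)
  if (d[3] != 2L) stop("expected 2 class channels")
  tg <- array(as.numeric(target), d[c(1, 2, 4)])
  pf <- probs[, , 2L, , drop = FALSE]
  dim(pf) <- d[c(1, 2, 4)]
  predFg <- pf > 0.5
  w <- ifelse(tg == 1,
              ifelse(predFg, weights[1], weights[2]),
              ifelse(predFg, weights[4], weights[3]))
  pt <- ifelse(tg == 1, pf, 1 - pf)
  nclamp <- sum(pt < eps)
  ptc <- pmax(pt, eps)
  n <- length(tg)
  loss <- sum(w * -log(ptc)) / n
  # d loss / d p_t = -w / p_t (zero where clamped); route to the true class
  gt <- ifelse(pt < eps, 0, -w / ptc) / n
  grad <- array(0, d)
  grad[, , 2L, ] <- ifelse(tg == 1, gt, 0)
  grad[, , 1L, ] <- ifelse(tg == 1, 0, gt)
  list(loss = loss, grad = grad, n_clamped = nclamp)
}

# Plain cross-entropy for K-class patch classification.
# probs: (1, 1, K, N); labels: integer 1..K.
classCrossEntropy <- function(probs, labels, eps = 1e-12) {
  d <- dim(probs)
  pm <- matrix(probs, d[3], d[4])
  idx <- cbind(labels, seq_along(labels))
  pt <- pmax(pm[idx], eps)
  loss <- -mean(log(pt))
  grad <- matrix(0, d[3], d[4])
  grad[idx] <- -1 / (pt * length(labels))
  list(loss = loss, grad = array(grad, d))
}

#' Forward an input through a network (inference mode)
#'
#' @param net a \code{\link{TrainedNetwork}}.
#' @param x input array \code{(H, W, C)} or batch \code{(H, W, C, N)}.
#' @return the output array \code{(H', W', C', N)}; batch-norm layers use
#'   their running statistics.
#' @export
forwardNetwork <- function(net, x) {
  netForward(net@spec, net@weights, x, training = FALSE)$out
}
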