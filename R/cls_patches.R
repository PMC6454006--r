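#' @include engine.R seg_net.R
NULL

# Ruderman RGB -> LMS -> l-alpha-beta transform constants (log10 LMS space).
.rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
.lms2rgb <- solve(.rgb2lms)
.lab1 <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
.lab1inv <- solve(.lab1)
.lmsEps <- 1e-4  # guard for log of near-black pixels

# (H, W, 3) RGB in [0,1] -> n x 3 matrix of l-alpha-beta values.
.toLab <- function(img) {
  d <- dim(img)
  rgb <- matrix(img, d[1] * d[2], 3L)
  lms <- pmax(rgb %*% t(.rgb2lms), .lmsEps)
  log10(lms) %*% t(.lab1)
}

.fromLab <- function(lab, d) {
  lms <- 10^(lab %*% t(.lab1inv))
  rgb <- lms %*% t(.lms2rgb)
  array(clamp01(rgb), d)
}

#' Color statistics of a stain-normalization target image
#'
#' @param image RGB array (H, W, 3) in \code{[0, 1]}.
#' @return a \code{\link{StainTarget}} holding per-channel mean and standard
#'   deviation in the l-alpha-beta space.
#' @export
stainTarget <- function(image) {
  lab <- .toLab(image)
  sds <- apply(lab, 2, stats::sd)
  sds <- pmax(sds, 1e-8)
  new("StainTarget", mean = colMeans(lab), sd = sds)
}

#' Reinhard stain normalization
#'
#' Maps an image's per-channel statistics in the decorrelated l-alpha-beta
#' color space onto those of a pre-defined target image: standardize each
#' channel by the source statistics, rescale to the target's, convert back to
#' RGB and clamp. Normalizing an image to its own statistics is the identity
#' up to rounding, and the mapping is idempotent for a fixed target.
#'
#' @param image RGB array (H, W, 3) in \code{[0, 1]}.
#' @param target a \code{\link{StainTarget}}.
#' @return the normalized RGB array.
#' @export
reinhardNormalize <- function(image, target) {
  stopifnot(is(target, "StainTarget"))
  lab <- .toLab(image)
  mu <- colMeans(lab)
  sds <- apply(lab, 2, stats::sd)
  low <- sds < 1e-8
  if (any(low)) sds[low] <- 1e-8  # zero-variance channel: shift only
  out <- sweep(lab, 2, mu, "-")
  out <- sweep(out, 2, target@sd / sds, "*")
  out <- sweep(out, 2, target@mean, "+")
  if (any(low))  # do not amplify a degenerate channel; match the mean only
    out[, low] <- sweep(lab[, low, drop = FALSE], 2, mu[low] -
                          target@mean[low], "-")
  .fromLab(out, dim(image))
}

#' Build the 32-layer residual patch classifier
#'
#' A reduced ResNet50 variant: 3x3 first convolution (stride 2), four stages
#' of pre-activation bottleneck units with unit counts (2, 3, 3, 2) — 10
#' units of 3 convolutions — global average pooling and a fully-connected
#' softmax head: 1 + 30 + 1 = 32 weighted layers (shortcut projections, as
#' usual in the ResNet naming, not counted). Consumes 224x224 RGB crops.
#'
#' @param nClasses output classes (3: ND, LUAD, LUSC).
#' @param width channel-width multiplier (1 = full size).
#' @param units per-stage bottleneck unit counts (must sum to 10 for a
#'   32-layer network).
#' @return a \code{\link{NetworkSpec}}.
#' @export
buildResNet32 <- function(nClasses = 3, width = 1, units = c(2L, 3L, 3L, 2L)) {
  b <- newGraphBuilder()
  base <- .chan(64, width)
  x <- addNode(b, "conv", 0L,
               list(k = 3L, cin = 3L, cout = base, stride = 2L, pad = "same",
                    groups = 1L), "classifier")
  cin <- base
  for (s in 1:4) {
    mid <- base * 2L^(s - 1L)
    cout <- 4L * mid
    for (u in seq_len(units[s])) {
      x <- addBottleneck(b, x, cin, mid, cout,
                         stride = if (u == 1L) 2L else 1L,
                         project = (u == 1L), part = "classifier")
      cin <- cout
    }
  }
  x <- addNode(b, "bn", x, list(cin = cin), "classifier")
  x <- addNode(b, "relu", x, list(), "classifier")
  x <- addNode(b, "gap", x, list(), "classifier")
  x <- addNode(b, "dense", x, list(cin = cin, out = nClasses), "classifier")
  x <- addNode(b, "softmax", x, list(), "classifier")
  finishGraph(b, sprintf("ResNet32 (width %g)", width),
              inputShape = c(224, 224, 3))
}

#' Classification-time augmentation: random crop, flip, rotation
#'
#' Uniformly random 224x224 crop of a 256x256 patch, random flips along both
#' axes, and a random multiple-of-90-degree rotation (all permutations of the
#' pixel grid, so the pixel multiset within the crop is preserved).
#'
#' @param patch RGB array (256, 256, 3).
#' @param cropSide output side (default 224).
#' @param seed optional RNG seed.
#' @param draw optional explicit draw: list(r0, c0 (0-based crop offsets),
#'   flipV, flipH, rot90 in 0:3).
#' @return RGB array (224, 224, 3).
#' @export
augmentCls <- function(patch, cropSide = 224L, seed = NULL, draw = NULL) {
  d <- dim(patch)
  if (length(d) != 3L || d[1] != 256L || d[2] != 256L)
    stop("expected a 256 x 256 x 3 patch")
  if (is.null(draw))
    draw <- withSeed(seed, list(
      r0 = sample.int(d[1] - cropSide + 1L, 1L) - 1L,
      c0 = sample.int(d[2] - cropSide + 1L, 1L) - 1L,
      flipV = runif(1) < 0.5, flipH = runif(1) < 0.5,
      rot90 = sample.int(4L, 1L) - 1L))
  x <- patch[draw$r0 + seq_len(cropSide), draw$c0 + seq_len(cropSide), ,
             drop = FALSE]
  if (draw$flipV) x <- x[rev(seq_len(cropSide)), , , drop = FALSE]
  if (draw$flipH) x <- x[, rev(seq_len(cropSide)), , drop = FALSE]
  for (k in seq_len(draw$rot90 %% 4L))
    x <- aperm(x, c(2, 1, 3))[rev(seq_len(cropSide)), , , drop = FALSE]
  x
}

.clsLevels <- c("ND", "LUAD", "LUSC")

# Assemble an input batch from 256-patches: stain-normalize (optional),
# augment (training) or center-crop (eval), optionally downscale.
.clsInput <- function(images, inputSide, cropSide = 224L, train = FALSE,
                      target = NULL) {
  n <- length(images)
  x <- array(0, c(inputSide, inputSide, 3, n))
  for (k in seq_len(n)) {
    img <- images[[k]]
    if (!is.null(target)) img <- reinhardNormalize(img, target)
    img <- if (train) augmentCls(img, cropSide)
           else centerCrop(img, cropSide)
    if (inputSide != cropSide)
      x[, , , k] <- .resize_bl_fwd(array(img, c(dim(img), 1L)),
                                   inputSide, inputSide)[, , , 1L]
    else x[, , , k] <- img
  }
  x
}

#' Patch classifier training configuration
#'
#' @param width channel-width multiplier of the 32-layer network.
#' @param inputSide side of the network input; 224 is the full-scale
#'   configuration, smaller values downscale the augmented crop (desk-scale
#'   runs).
#' @param epochs training epochs (every epoch is checkpointed; the epoch with
#'   the greatest validation accuracy is selected, ties to the earliest).
#' @param batchSize minibatch size.
#' @param lr Adam learning rate.
#' @param l2 L2 regularization factor.
#' @param valFraction fraction of patches held out for validation.
#' @param stainNormalize normalize patches to a shared Reinhard target
#'   (statistics of the first training patch) before training/inference.
#' @return list of class \code{"ClsTrainConfig"}.
#' @export
clsTrainConfig <- function(width = 1, inputSide = 224L, epochs = 10L,
                           batchSize = 32L, lr = 1e-4, l2 = 1e-5,
                           valFraction = 0.25, stainNormalize = FALSE) {
  structure(list(width = width, inputSide = as.integer(inputSide),
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), lr = lr, l2 = l2,
                 valFraction = valFraction, stainNormalize = stainNormalize),
            class = "ClsTrainConfig")
}

#' Train the three-class patch classifier
#'
#' Optimizes the 32-layer residual network on labeled 256x256 patches
#' (classes ND / LUAD / LUSC) with Adam, random crop/flip/rotation
#' augmentation, and a held-out validation split. All epoch checkpoints'
#' validation accuracies are recorded; the returned weights are those of the
#' epoch with the greatest validation accuracy (ties to the earliest epoch).
#'
#' @param patches list of patch records (fields \code{image}, \code{label})
#'   or a list of images with \code{labels} given separately.
#' @param labels optional character vector of labels parallel to
#'   \code{patches}.
#' @param config a \code{\link{clsTrainConfig}}.
#' @param seed RNG seed.
#' @param verbose print per-epoch validation accuracy.
#' @return a \code{\link{TrainedNetwork}}; \code{history} holds per-epoch
#'   training loss and validation accuracy plus \code{selectedEpoch}.
#' @export
trainPatchClassifier <- function(patches, labels = NULL,
                                 config = clsTrainConfig(), seed = 1L,
                                 verbose = FALSE) {
  if (is.null(labels))
    labels <- vapply(patches, `[[`, "", "label")
  images <- lapply(patches, function(p) if (is.list(p)) p$image else p)
  y <- match(labels, .clsLevels)
  if (anyNA(y)) stop("labels must be ND, LUAD or LUSC")
  if (!all(.clsLevels %in% labels))
    stop("at least one patch per class (ND, LUAD, LUSC) is required")
  spec <- buildResNet32(3L, config$width)
  weights <- initNetworkWeights(spec, seed)
  target <- if (config$stainNormalize) stainTarget(images[[1]]) else NULL
  withSeed(seed + 1L, {
    n <- length(images)
    nVal <- max(1L, round(config$valFraction * n))
    valIdx <- sample.int(n, nVal)
    trIdx <- setdiff(seq_len(n), valIdx)
    if (length(trIdx) == 0L) stop("no training patches left")
    state <- adamInit()
    history <- list(loss = numeric(0), valAccuracy = numeric(0))
    checkpoints <- list()
    steps <- max(1L, ceiling(length(trIdx) / config$batchSize))
    for (ep in seq_len(config$epochs)) {
      epLoss <- 0
      for (st in seq_len(steps)) {
        idx <- sample(trIdx, min(config$batchSize, length(trIdx)),
                      replace = length(trIdx) < config$batchSize)
        x <- .clsInput(images[idx], config$inputSide, train = TRUE,
                       target = target)
        fw <- netForward(spec, weights, x, training = TRUE)
        ls <- classCrossEntropy(fw$out, y[idx])
        grads <- netBackward(spec, weights, fw, ls$grad)
        upd <- adamStep(weights, grads, state, config$lr, l2 = config$l2)
        weights <- updateRunningStats(upd$weights, fw$batchStats)
        state <- upd$state
        epLoss <- epLoss + ls$loss
      }
      xv <- .clsInput(images[valIdx], config$inputSide, train = FALSE,
                      target = target)
      pv <- netForward(spec, weights, xv, training = FALSE)$out
      pred <- apply(matrix(pv, 3L, length(valIdx)), 2, which.max)
      acc <- mean(pred == y[valIdx])
      history$loss <- c(history$loss, epLoss / steps)
      history$valAccuracy <- c(history$valAccuracy, acc)
      checkpoints[[ep]] <- weights
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val accuracy %.3f",
                        ep, epLoss / steps, acc))
    }
    sel <- which.max(history$valAccuracy)  # earliest on ties
    history$selectedEpoch <- sel
    new("TrainedNetwork", spec = spec, weights = checkpoints[[sel]],
        config = c(unclass(config), list(seed = seed,
                                         stainTarget = target)),
        history = history)
  })
}

#' Class probabilities for one patch
#'
#' Deterministic inference: center-crop the 256x256 patch to 224x224 (no
#' augmentation randomness), stain-normalize if the classifier was trained
#' that way, and forward through the network.
#'
#' @param net a \code{\link{TrainedNetwork}} from
#'   \code{\link{trainPatchClassifier}}.
#' @param patch RGB array (256, 256, 3).
#' @return named probability 3-vector (ND, LUAD, LUSC) summing to 1.
#' @export
predictPatch <- function(net, patch) {
  cfg <- net@config
  x <- .clsInput(list(patch), cfg$inputSide %||% 224L,
                 target = cfg$stainTarget)
  p <- forwardNetwork(net, x)
  stats::setNames(as.vector(p), .clsLevels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
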