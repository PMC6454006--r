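#' @include engine.R
NULL

# ---------------------------------------------------------------------------
# DRAN / MDRAN architecture builders.
#
# Contracting path: pre-activated 50-layer residual network with a 7x7
# valid stride-1 stem (no max pool), stage strides (1, 2, 2, 2) and stage
# output channels (256, 512, 1024, 2048) x width. Expanding path: 2x2
# stride-2 transpose convolution, three valid-padded decoders with grouped
# middle convolutions (Table-1 layout), nearest-neighbor x2 resizing, and
# addition merges with center-cropped contracting skips. For a 102x102 input
# the output map is 54x54.
# ---------------------------------------------------------------------------

.chan <- function(n, width) {
  v <- as.integer(round(n * width))
  if (v < 1L) stop("width too small for ", n, " channels")
  v
}

# One pre-activation bottleneck unit. Returns the output node id.
addBottleneck <- function(b, x, cin, mid, cout, stride, project, part) {
  h <- addNode(b, "bn", x, list(cin = cin), part)
  h <- addNode(b, "relu", h, list(), part)
  sc <- if (project)
    addNode(b, "conv", h, list(k = 1L, cin = cin, cout = cout,
                               stride = stride, pad = "same", groups = 1L,
                               role = "projection"), part)
  else x
  m <- addNode(b, "conv", h, list(k = 1L, cin = cin, cout = mid, stride = 1L,
                                  pad = "same", groups = 1L), part)
  m <- addNode(b, "bn", m, list(cin = mid), part)
  m <- addNode(b, "relu", m, list(), part)
  m <- addNode(b, "conv", m, list(k = 3L, cin = mid, cout = mid,
                                  stride = stride, pad = "same",
                                  groups = 1L), part)
  m <- addNode(b, "bn", m, list(cin = mid), part)
  m <- addNode(b, "relu", m, list(), part)
  m <- addNode(b, "conv", m, list(k = 1L, cin = mid, cout = cout, stride = 1L,
                                  pad = "same", groups = 1L), part)
  addNode(b, "add", c(m, sc), list(), part)
}

# Pre-activated residual contracting path (stem + 4 stages). Returns the ids
# and channel counts of the four stage outputs.
addContractingPath <- function(b, input, width = 1, part = "contracting",
                               units = c(3L, 4L, 6L, 3L)) {
  base <- .chan(64, width)
  x <- addNode(b, "conv", input,
               list(k = 7L, cin = 3L, cout = base, stride = 1L,
                    pad = "valid", groups = 1L), part)
  stages <- integer(4)
  chans <- integer(4)
  cin <- base
  for (s in 1:4) {
    mid <- base * 2L^(s - 1L)
    cout <- 4L * mid
    stride <- if (s == 1L) 1L else 2L
    for (u in seq_len(units[s])) {
      x <- addBottleneck(b, x, cin, mid, cout,
                         stride = if (u == 1L) stride else 1L,
                         project = (u == 1L), part = part)
      cin <- cout
    }
    stages[s] <- x
    chans[s] <- cout
  }
  x <- addNode(b, "bn", x, list(cin = cin), part)
  x <- addNode(b, "relu", x, list(), part)
  list(out = x, stages = stages, chans = chans)
}

# A Table-1 decoder: 5x5 conv -> BN/ReLU -> grouped 3x3 conv -> BN/ReLU ->
# 1x1 conv (linear). Valid padding for decoders 1-3; decoder4 is same-padded.
addDecoder <- function(b, x, cin, cmid, groups, cout, pad, part) {
  x <- addNode(b, "conv", x, list(k = 5L, cin = cin, cout = cmid, stride = 1L,
                                  pad = pad, groups = 1L), part)
  x <- addNode(b, "bn", x, list(cin = cmid), part)
  x <- addNode(b, "relu", x, list(), part)
  if (cmid %% groups != 0L) stop("groups must divide channels")
  x <- addNode(b, "conv", x, list(k = 3L, cin = cmid, cout = cmid,
                                  stride = 1L, pad = pad, groups = groups),
               part)
  x <- addNode(b, "bn", x, list(cin = cmid), part)
  x <- addNode(b, "relu", x, list(), part)
  addNode(b, "conv", x, list(k = 1L, cin = cmid, cout = cout, stride = 1L,
                             pad = pad, groups = 1L), part)
}

# The DRAN body (contracting + expanding path up to the decoder1 output,
# 128 x width channels). Returns node ids; `first`/`last` delimit the body's
# node range for weight transplantation into multiscale branches.
addDranBody <- function(b, input, width) {
  first <- length(b$layers) + 1L
  cp <- addContractingPath(b, input, width)
  w <- function(n) .chan(n, width)
  x <- addNode(b, "tconv", cp$out,
               list(cin = w(2048), cout = w(1024)), "expanding")
  x <- addNode(b, "add", c(x, cp$stages[3]), list(), "expanding")
  x <- addDecoder(b, x, w(1024), w(1024), w(256), w(512), "valid", "expanding")
  x <- addNode(b, "resize", x, list(factor = 2, mode = "nearest"), "expanding")
  s2 <- addNode(b, "crop_like", c(cp$stages[2], x), list(), "expanding")
  x <- addNode(b, "add", c(x, s2), list(), "expanding")
  x <- addDecoder(b, x, w(512), w(512), w(128), w(256), "valid", "expanding")
  x <- addNode(b, "resize", x, list(factor = 2, mode = "nearest"), "expanding")
  s1 <- addNode(b, "crop_like", c(cp$stages[1], x), list(), "expanding")
  x <- addNode(b, "add", c(x, s1), list(), "expanding")
  x <- addDecoder(b, x, w(256), w(256), w(64), w(128), "valid", "expanding")
  list(out = x, first = first, last = length(b$layers))
}

#' Build the contracting path alone
#'
#' Pre-activated 50-layer residual feature extractor with a valid 7x7
#' stride-1 stem, no max pooling, stage strides (1, 2, 2, 2) and stage output
#' channels (256, 512, 1024, 2048) scaled by \code{width}. A 102x102 input
#' produces stage spatial sides 96, 96, 48, 24, 12.
#'
#' @param width channel-width multiplier (1 = full size; powers of two below
#'   one give the reduced variants used for desk-scale training).
#' @return a \code{\link{NetworkSpec}} ending at the final pre-activation.
#' @export
buildContractingPath <- function(width = 1) {
  b <- newGraphBuilder()
  addContractingPath(b, 0L, width)
  finishGraph(b, sprintf("contracting-path (width %g)", width))
}

#' Build a single-scale deep residual aggregation network (DRAN)
#'
#' Encoder-decoder network for binary segmentation of nucleus blobs or
#' boundaries: residual contracting path, then a 2x2 stride-2 transpose
#' convolution, three valid-padded decoders with grouped middle convolutions,
#' nearest-neighbor x2 upsampling, and addition merges with center-cropped
#' contracting skips; a 1x1 convolution and softmax produce per-pixel class
#' probabilities. Maps a 102x102 RGB input to a 54x54 map.
#'
#' @param nClasses output classes (2: background vs object).
#' @param width channel-width multiplier.
#' @return a \code{\link{NetworkSpec}}.
#' @export
buildDRAN <- function(nClasses = 2, width = 1) {
  b <- newGraphBuilder()
  body <- addDranBody(b, 0L, width)
  x <- addNode(b, "conv", body$out,
               list(k = 1L, cin = .chan(128, width), cout = nClasses,
                    stride = 1L, pad = "valid", groups = 1L), "expanding")
  x <- addNode(b, "softmax", x, list(), "expanding")
  spec <- finishGraph(b, sprintf("DRAN (width %g)", width),
                      inputShape = c(102, 102, 3),
                      meta = list(body = c(body$first, body$last)))
  sh <- propagateShapes(spec, c(102, 102, 3))
  out <- sh[nrow(sh), ]
  if (!all(out == c(54, 54, nClasses)))
    stop("DRAN build error: 102x102 input propagates to ",
         paste(out, collapse = "x"), ", expected 54x54x", nClasses)
  spec
}

#' Build the multiscale DRAN (MDRAN)
#'
#' Three DRAN bodies process the input at x0.5, x1 and x2 scale (the input is
#' resized internally); each branch's decoder1 output (128 x width channels)
#' is resized to the x1 output grid, the three are merged by element-wise
#' addition, and a same-padded decoder4 (5x5 to 256 x width channels, grouped
#' 3x3, 1x1) with softmax produces the final map on the x1 grid (54x54 for a
#' 102x102 input).
#'
#' @inheritParams buildDRAN
#' @return a \code{\link{NetworkSpec}} with branch node maps in \code{meta}.
#' @export
buildMDRAN <- function(nClasses = 2, width = 1) {
  b <- newGraphBuilder()
  x05 <- addNode(b, "resize", 0L, list(factor = 0.5, mode = "bilinear"),
                 "input")
  x2 <- addNode(b, "resize", 0L, list(factor = 2, mode = "bilinear"), "input")
  b05 <- addDranBody(b, x05, width)
  b1 <- addDranBody(b, 0L, width)
  b2 <- addDranBody(b, x2, width)
  r05 <- addNode(b, "resize_like", c(b05$out, b1$out),
                 list(mode = "nearest"), "decoder4")
  r2 <- addNode(b, "resize_like", c(b2$out, b1$out),
                list(mode = "nearest"), "decoder4")
  x <- addNode(b, "add", c(b1$out, r05, r2), list(), "decoder4")
  x <- addDecoder(b, x, .chan(128, width), .chan(256, width),
                  .chan(64, width), nClasses, "same", "decoder4")
  x <- addNode(b, "softmax", x, list(), "decoder4")
  spec <- finishGraph(
    b, sprintf("MDRAN (width %g)", width), inputShape = c(102, 102, 3),
    meta = list(branches = list(
      x0.5 = c(b05$first, b05$last),
      x1 = c(b1$first, b1$last),
      x2 = c(b2$first, b2$last))))
  sh <- propagateShapes(spec, c(102, 102, 3))
  out <- sh[nrow(sh), ]
  if (!all(out == c(54, 54, nClasses)))
    stop("MDRAN build error: output ", paste(out, collapse = "x"))
  spec
}

#' Assemble an MDRAN from three pretrained single-scale networks
#'
#' Each branch of the multiscale network is loaded with the weights of a
#' pretrained DRAN (trained at x0.5, x1 and x2 scale); decoder4 is freshly
#' initialized.
#'
#' @param branches named list with elements \code{x0.5}, \code{x1}, \code{x2},
#'   each a \code{\link{TrainedNetwork}} from \code{\link{trainDRAN}} built at
#'   the same \code{width}.
#' @param nClasses,width as in \code{\link{buildMDRAN}}.
#' @param seed seed for decoder4 initialization.
#' @return a \code{\link{TrainedNetwork}} (untrained decoder4).
#' @export
mdranFromBranches <- function(branches, nClasses = 2, width = 1, seed = 1L) {
  need <- c("x0.5", "x1", "x2")
  if (!all(need %in% names(branches)))
    stop("branches must be a named list with elements x0.5, x1, x2")
  spec <- buildMDRAN(nClasses, width)
  weights <- initNetworkWeights(spec, seed)
  for (nm in need) {
    tn <- branches[[nm]]
    if (!is(tn, "TrainedNetwork")) stop("branch ", nm, " has no weights")
    rng <- spec@meta$branches[[nm]]
    src <- tn@spec@meta$body
    if (is.null(src)) stop("branch ", nm, " is not a DRAN")
    if (diff(rng) != diff(src)) stop("branch width mismatch for ", nm)
    # single-bracket assignment: weightless nodes (relu, add, ...) hold NULL
    # and must stay as list slots
    weights[rng[1] + 0:diff(rng)] <- tn@weights[src[1] + 0:diff(rng)]
  }
  new("TrainedNetwork", spec = spec, weights = weights,
      config = list(width = width, nClasses = nClasses), history = list())
}

# ---------------------------------------------------------------------------
# Training schedules
# ---------------------------------------------------------------------------

#' Two-phase DRAN training schedule
#'
#' Phase 1 (35 epochs): contracting path frozen, learning rate 1.0e-4
#' dropping to 5.0e-5 / 1.0e-5 / 7.5e-6 at epochs 1 / 15 / 25, reaching
#' 5.0e-6 at the phase boundary. Phase 2 (40 epochs): whole network
#' trainable at 5.0e-6. Adam (beta1 0.9, beta2 0.999, eps 1e-8), batch 32,
#' L2 factor 1e-5.
#'
#' @param epochs1,epochs2 phase lengths (defaults 35 / 40); shrink for smoke
#'   runs.
#' @return schedule list consumed by \code{\link{trainDRAN}}.
#' @export
dranSchedule <- function(epochs1 = 35L, epochs2 = 40L) {
  list(
    phases = list(
      list(epochs = epochs1, trainable = "expanding",
           lr = c("0" = 1e-4, "1" = 5e-5, "15" = 1e-5, "25" = 7.5e-6)),
      list(epochs = epochs2, trainable = c("contracting", "expanding"),
           lr = c("0" = 5e-6))),
    batchSize = 32L, l2 = 1e-5)
}

#' MDRAN fine-tuning schedule
#'
#' Phase A (10 epochs): only decoder4 trains, learning rate 1.0e-4. Phase B
#' (35 epochs): decoder4 plus the three expanding paths train, learning rate
#' 1.0e-4 dropping to 1.0e-5 / 1.0e-6 at epochs 15 / 30; the contracting
#' paths stay frozen throughout.
#'
#' @param epochsA,epochsB phase lengths (defaults 10 / 35).
#' @return schedule list consumed by \code{\link{trainMDRAN}}.
#' @export
mdranSchedule <- function(epochsA = 10L, epochsB = 35L) {
  list(
    phases = list(
      list(epochs = epochsA, trainable = "decoder4", lr = c("0" = 1e-4)),
      list(epochs = epochsB, trainable = c("decoder4", "expanding"),
           lr = c("0" = 1e-4, "15" = 1e-5, "30" = 1e-6))),
    batchSize = 32L, l2 = 1e-5)
}

#' Learning rate of a schedule phase at a given epoch
#'
#' @param phase one element of a schedule's \code{phases}.
#' @param epoch 0-based epoch index within the phase.
#' @return the learning rate in force (last breakpoint at or before
#'   \code{epoch}).
#' @export
scheduleLR <- function(phase, epoch) {
  bp <- as.integer(names(phase$lr))
  unname(phase$lr[max(which(bp <= epoch))])
}

# ---------------------------------------------------------------------------
# Training loops
# ---------------------------------------------------------------------------

# Assemble (input, target) batch arrays from segmentation patches.
.segBatch <- function(patches, idx, task, inSide = 102L, outSide = 54L) {
  n <- length(idx)
  p1 <- patches[[idx[1]]]
  x <- array(0, c(inSide, inSide, 3, n))
  tg <- array(0, c(outSide, outSide, n))
  key <- if (task == "blob") "blob" else "border"
  for (k in seq_len(n)) {
    p <- patches[[idx[k]]]
    x[, , , k] <- centerCrop(p$image, inSide)
    tg[, , k] <- centerCrop(p[[key]], outSide)
  }
  list(x = x, target = tg)
}

.runPhases <- function(spec, weights, patches, task, schedule, seed,
                       stepsPerEpoch, lossWeights, verbose) {
  history <- list(loss = numeric(0), lr = numeric(0), phase = integer(0))
  state <- adamInit()
  bs <- schedule$batchSize
  if (is.null(stepsPerEpoch))
    stepsPerEpoch <- max(1L, ceiling(length(patches) / bs))
  parts <- vapply(spec@layers, `[[`, "", "part")
  withSeed(seed, {
    for (ph in seq_along(schedule$phases)) {
      phase <- schedule$phases[[ph]]
      bnNodes <- which(parts %in% phase$trainable)
      for (ep in seq_len(phase$epochs) - 1L) {
        lr <- scheduleLR(phase, ep)
        epLoss <- 0
        for (st in seq_len(stepsPerEpoch)) {
          idx <- sample.int(length(patches), min(bs, length(patches)),
                            replace = length(patches) < bs)
          batch <- .segBatch(patches, idx, task)
          fw <- netForward(spec, weights, batch$x, training = TRUE)
          ls <- weightedLoss(fw$out, batch$target, lossWeights)
          grads <- netBackward(spec, weights, fw, ls$grad,
                               trainable = phase$trainable)
          upd <- adamStep(weights, grads, state, lr, l2 = schedule$l2)
          weights <- updateRunningStats(upd$weights, fw$batchStats,
                                        nodes = bnNodes)
          state <- upd$state
          epLoss <- epLoss + ls$loss + schedule$l2 * l2Penalty(weights)
        }
        history$loss <- c(history$loss, epLoss / stepsPerEpoch)
        history$lr <- c(history$lr, lr)
        history$phase <- c(history$phase, ph)
        if (verbose)
          message(sprintf("phase %d epoch %d: loss %.4f (lr %.1e)",
                          ph, ep, epLoss / stepsPerEpoch, lr))
      }
    }
  })
  list(weights = weights, history = history)
}

#' Train a single-scale segmentation network
#'
#' Optimizes a DRAN for nucleus blob or boundary prediction with Adam under
#' the two-phase schedule: phase 1 trains the expanding path only (contracting
#' path frozen), phase 2 trains everything. Inputs are the centered 102x102
#' crops of the 200x200 patches; targets the centered 54x54 crops. The border
#' task uses the 5/6/1/4 class-weighted loss; the blob task unweighted
#' cross-entropy.
#'
#' @param patches list of segmentation patches (elements \code{image},
#'   \code{blob}, \code{border}), e.g. from \code{\link{extractNBL}} /
#'   \code{\link{extractNBD}}.
#' @param task \code{"blob"} or \code{"border"}.
#' @param schedule from \code{\link{dranSchedule}} (shrink epochs for smoke
#'   runs).
#' @param seed RNG seed for initialization and batch sampling.
#' @param width channel-width multiplier.
#' @param stepsPerEpoch optimization steps per epoch (default: one pass).
#' @param pretrainedContracting optional \code{\link{TrainedNetwork}} whose
#'   contracting-path weights are injected before training (hook for
#'   externally pretrained encoders); default He initialization everywhere.
#' @param verbose print per-epoch loss.
#' @return a \code{\link{TrainedNetwork}} with per-epoch \code{history}
#'   (loss, learning rate, phase).
#' @export
trainDRAN <- function(patches, task = c("blob", "border"),
                      schedule = dranSchedule(), seed = 1L, width = 1,
                      stepsPerEpoch = NULL, pretrainedContracting = NULL,
                      verbose = FALSE) {
  task <- match.arg(task)
  if (length(patches) == 0L) stop("empty training dataset")
  spec <- buildDRAN(2L, width)
  weights <- initNetworkWeights(spec, seed)
  if (!is.null(pretrainedContracting)) {
    src <- pretrainedContracting@weights
    for (i in seq_along(spec@layers))
      if (spec@layers[[i]]$part == "contracting" && i <= length(src) &&
          !is.null(src[[i]]))
        weights[[i]] <- src[[i]]
  }
  lw <- if (task == "border") c(5, 6, 1, 4) else c(1, 1, 1, 1)
  res <- .runPhases(spec, weights, patches, task, schedule, seed,
                    stepsPerEpoch, lw, verbose)
  new("TrainedNetwork", spec = spec, weights = res$weights,
      config = list(task = task, width = width, schedule = schedule,
                    seed = seed),
      history = res$history)
}

#' Fine-tune the multiscale network from pretrained branches
#'
#' Phase A trains only decoder4 (all three branches frozen); phase B
#' additionally trains the three expanding paths. Contracting paths never
#' update.
#'
#' @param branches named list (\code{x0.5}, \code{x1}, \code{x2}) of
#'   pretrained \code{\link{TrainedNetwork}} DRANs.
#' @inheritParams trainDRAN
#' @return a \code{\link{TrainedNetwork}}.
#' @export
trainMDRAN <- function(branches, patches, task = c("blob", "border"),
                       schedule = mdranSchedule(), seed = 1L, width = 1,
                       stepsPerEpoch = NULL, verbose = FALSE) {
  task <- match.arg(task)
  if (length(patches) == 0L) stop("empty training dataset")
  tn <- mdranFromBranches(branches, 2L, width, seed)
  lw <- if (task == "border") c(5, 6, 1, 4) else c(1, 1, 1, 1)
  res <- .runPhases(tn@spec, tn@weights, patches, task, schedule, seed,
                    stepsPerEpoch, lw, verbose)
  new("TrainedNetwork", spec = tn@spec, weights = res$weights,
      config = list(task = task, width = width, schedule = schedule,
                    seed = seed),
      history = res$history)
}

#' Wrap a randomly initialized architecture as a network object
#'
#' @param spec a \code{\link{NetworkSpec}}.
#' @param seed initialization seed.
#' @return a \code{\link{TrainedNetwork}} with He-initialized weights.
#' @export
randomNetwork <- function(spec, seed = 1L) {
  new("TrainedNetwork", spec = spec,
      weights = initNetworkWeights(spec, seed),
      config = list(seed = seed), history = list())
}
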