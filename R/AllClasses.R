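#' @include histoseg-package.R
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Tissue tile with optional labeled instance mask
#'
#' An RGB tissue image tile together with its (optional) labeled nucleus mask
#' and physical-scale metadata. Labeled masks are integer matrices in which 0
#' is background and each positive id is one nucleus instance.
#'
#' @slot image numeric array \code{(H, W, 3)}, intensities in \code{[0, 1]}.
#' @slot mask integer matrix \code{(H, W)} of instance ids, or \code{NULL}.
#' @slot mpp microns per pixel (> 0).
#' @slot magnification scanner magnification, \code{"20x"} or \code{"40x"}.
#' @slot id tile identifier.
#' @export
setClass("NucleiTile",
  representation(image = "array", mask = "matrixOrNULL", mpp = "numeric",
                 magnification = "character", id = "character"),
  prototype(mpp = 0.25, magnification = "40x", id = "tile")
)

setValidity("NucleiTile", function(object) {
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L)
    return("image must be an (H, W, 3) array")
  if (!is.null(object@mask) && !identical(dim(object@mask), d[1:2]))
    return("mask dimensions must match image")
  if (length(object@mpp) != 1L || !is.finite(object@mpp) || object@mpp <= 0)
    return("mpp must be a single positive number")
  if (!object@magnification %in% c("20x", "40x"))
    return("magnification must be '20x' or '40x'")
  TRUE
})

#' Per-slide class probability maps
#'
#' Three aligned grids over a slide's patch grid, one per class (ND, LUAD,
#' LUSC); each cell holds that patch's class probability and the three grids
#' sum to 1 per cell.
#'
#' @slot nd,luad,lusc numeric matrices of identical dimension.
#' @export
setClass("ProbabilityMaps",
  representation(nd = "matrix", luad = "matrix", lusc = "matrix"))

setValidity("ProbabilityMaps", function(object) {
  if (!identical(dim(object@nd), dim(object@luad)) ||
      !identical(dim(object@nd), dim(object@lusc)))
    return("the three maps must be congruent")
  s <- object@nd + object@luad + object@lusc
  if (length(s) && max(abs(s - 1)) > 1e-6)
    return("per-cell class probabilities must sum to 1")
  rng <- range(object@nd, object@luad, object@lusc)
  if (length(s) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
    return("probabilities must lie in [0, 1]")
  TRUE
})

#' Declarative network architecture
#'
#' A layered network f = f_L o ... o f_1 represented as a directed acyclic
#' graph of layer nodes. Each node is a list with fields \code{id},
#' \code{kind}, \code{inputs} (producer node ids; 0 refers to the network
#' input), \code{params}, and \code{part} (a tag used by training schedules to
#' freeze parameter groups). Build networks with \code{\link{buildDRAN}},
#' \code{\link{buildMDRAN}}, or \code{\link{buildResNet32}}.
#'
#' @slot layers list of layer nodes in topological order.
#' @slot name network name.
#' @slot inputShape expected input shape \code{c(H, W, C)} (NA = flexible).
#' @slot meta builder metadata (e.g. branch-to-node maps for multiscale nets).
#' @export
setClass("NetworkSpec",
  representation(layers = "list", name = "character", inputShape = "numeric",
                 meta = "list"),
  prototype(meta = list()))

setValidity("NetworkSpec", function(object) {
  for (i in seq_along(object@layers)) {
    ly <- object@layers[[i]]
    if (!all(c("id", "kind", "inputs", "params") %in% names(ly)))
      return("each layer needs id, kind, inputs, params")
    if (ly$id != i) return("layer ids must be 1..L in order")
    if (any(ly$inputs >= i)) return("layer inputs must precede the layer")
  }
  TRUE
})

#' A network together with its weights
#'
#' @slot spec the \code{\link{NetworkSpec}}.
#' @slot weights per-node weight lists (conv kernels, biases, batch-norm
#'   parameters and running statistics).
#' @slot config list of training/inference settings.
#' @slot history per-epoch training log (loss, learning rate).
#' @export
setClass("TrainedNetwork",
  representation(spec = "NetworkSpec", weights = "list", config = "list",
                 history = "list"))

#' Reinhard stain-normalization target
#'
#' Per-channel mean and standard deviation of a reference image in the
#' decorrelated l-alpha-beta color space.
#'
#' @slot mean,sd numeric length-3 vectors of channel statistics.
#' @export
setClass("StainTarget", representation(mean = "numeric", sd = "numeric"))

setValidity("StainTarget", function(object) {
  if (length(object@mean) != 3L || length(object@sd) != 3L)
    return("mean and sd must have length 3")
  if (any(!is.finite(object@mean)) || any(!is.finite(object@sd)))
    return("statistics must be finite")
  if (any(object@sd <= 0)) return("standard deviations must be positive")
  TRUE
})

#' Segmentation score report
#'
#' Per-tile DICE_1 / DICE_2 / tile scores and their dataset means. The tile
#' score is exactly the mean of the two Dice coefficients.
#'
#' @slot perTile data.frame with columns \code{tile}, \code{dice1},
#'   \code{dice2}, \code{score}.
#' @slot dice1,dice2,score dataset means.
#' @export
setClass("ScoreReport",
  representation(perTile = "data.frame", dice1 = "numeric", dice2 = "numeric",
                 score = "numeric"))

setValidity("ScoreReport", function(object) {
  pt <- object@perTile
  if (!all(c("tile", "dice1", "dice2", "score") %in% names(pt)))
    return("perTile needs columns tile, dice1, dice2, score")
  if (nrow(pt) && max(abs(pt$score - (pt$dice1 + pt$dice2) / 2)) > 1e-12)
    return("tile score must equal (dice1 + dice2) / 2")
  TRUE
})
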