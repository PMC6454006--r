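#' @include AllClasses.R
NULL

#' Construct a NucleiTile
#'
#' @param image numeric array \code{(H, W, 3)} with values in \code{[0, 1]}.
#' @param mask integer labeled mask matrix or \code{NULL}.
#' @param mpp microns per pixel; if missing, derived from \code{magnification}
#'   (0.25 at 40x, 0.5 at 20x — standard scanner conventions).
#' @param magnification \code{"40x"} (default) or \code{"20x"}.
#' @param id tile identifier.
#' @return a \code{\link{NucleiTile}}.
#' @export
NucleiTile <- function(image, mask = NULL, mpp = NULL,
                       magnification = "40x", id = "tile") {
  if (is.null(mpp)) mpp <- defaultMpp(magnification)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    storage.mode(mask) <- "integer"
  }
  new("NucleiTile", image = image, mask = mask, mpp = mpp,
      magnification = magnification, id = id)
}

#' Default microns-per-pixel for a magnification
#'
#' @param magnification \code{"40x"} or \code{"20x"}.
#' @return microns per pixel (0.25 at 40x, 0.5 at 20x).
#' @export
defaultMpp <- function(magnification) {
  switch(magnification, "40x" = 0.25, "20x" = 0.5,
         stop("unknown magnification: ", magnification))
}

#' @rdname NucleiTile-class
#' @param object,x a \code{NucleiTile}.
#' @export
setGeneric("tileImage", function(x) standardGeneric("tileImage"))
#' @rdname NucleiTile-class
#' @export
setMethod("tileImage", "NucleiTile", function(x) x@image)

#' @rdname NucleiTile-class
#' @export
setGeneric("tileMask", function(x) standardGeneric("tileMask"))
#' @rdname NucleiTile-class
#' @export
setMethod("tileMask", "NucleiTile", function(x) x@mask)

#' @rdname NucleiTile-class
#' @export
setGeneric("tileMpp", function(x) standardGeneric("tileMpp"))
#' @rdname NucleiTile-class
#' @export
setMethod("tileMpp", "NucleiTile", function(x) x@mpp)

#' @rdname NucleiTile-class
#' @export
setGeneric("tileId", function(x) standardGeneric("tileId"))
#' @rdname NucleiTile-class
#' @export
setMethod("tileId", "NucleiTile", function(x) x@id)

setMethod("show", "NucleiTile", function(object) {
  d <- dim(object@image)
  cat(sprintf("NucleiTile '%s': %d x %d px, %s (%.2f um/px), %s\n",
              object@id, d[1], d[2], object@magnification, object@mpp,
              if (is.null(object@mask)) "no mask"
              else sprintf("%d nuclei", maskObjectCount(object@mask))))
})

#' Construct per-slide probability maps
#'
#' @param nd,luad,lusc numeric matrices of per-patch class probabilities.
#' @return a \code{\link{ProbabilityMaps}}.
#' @export
ProbabilityMaps <- function(nd, luad, lusc) {
  new("ProbabilityMaps", nd = as.matrix(nd), luad = as.matrix(luad),
      lusc = as.matrix(lusc))
}

#' @rdname ProbabilityMaps-class
#' @param x a \code{ProbabilityMaps}.
#' @param class one of \code{"ND"}, \code{"LUAD"}, \code{"LUSC"}.
#' @export
setGeneric("classMap", function(x, class) standardGeneric("classMap"))
#' @rdname ProbabilityMaps-class
#' @export
setMethod("classMap", "ProbabilityMaps", function(x, class) {
  switch(toupper(class), ND = x@nd, LUAD = x@luad, LUSC = x@lusc,
         stop("unknown class: ", class))
})

setMethod("show", "ProbabilityMaps", function(object) {
  d <- dim(object@nd)
  am <- argmaxMaps(object)
  cat(sprintf(
    "ProbabilityMaps: %d x %d patch grid (argmax: %d ND, %d LUAD, %d LUSC)\n",
    d[1], d[2], sum(am == 1L), sum(am == 2L), sum(am == 3L)))
})

setMethod("show", "NetworkSpec", function(object) {
  kinds <- vapply(object@layers, `[[`, "", "kind")
  cat(sprintf("NetworkSpec '%s': %d nodes, %d weighted layers\n",
              object@name, length(object@layers),
              countWeightedLayers(object)))
  tab <- table(kinds)
  cat("  ", paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                  collapse = " "), "\n")
})

setMethod("show", "TrainedNetwork", function(object) {
  cat(sprintf("TrainedNetwork '%s': %s parameters, %d epochs logged\n",
              object@spec@name,
              format(parameterCount(object), big.mark = ","),
              length(object@history$loss)))
})

setMethod("show", "StainTarget", function(object) {
  cat("StainTarget (l-alpha-beta): mean",
      paste(sprintf("%.3f", object@mean), collapse = "/"),
      " sd", paste(sprintf("%.3f", object@sd), collapse = "/"), "\n")
})

setMethod("show", "ScoreReport", function(object) {
  cat(sprintf("ScoreReport: %d tiles, DICE_1 %.4f, DICE_2 %.4f, score %.3f\n",
              nrow(object@perTile), object@dice1, object@dice2,
              printedScore(object@score)))
})

#' Number of instances in a labeled mask
#'
#' @param mask integer labeled mask.
#' @return count of distinct positive ids.
#' @export
maskObjectCount <- function(mask) length(unique(mask[mask > 0L]))
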