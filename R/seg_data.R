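#' @include utils.R AllGenerics.R
NULL

# A segmentation patch is a plain list: image (200x200x3), blob and border
# binary target matrices (200x200), tag ("NBL"/"NBD"/"SN"), tile (source
# id), offset (0-based (row, col) of the patch in the tile).

.newSegPatch <- function(image, blob, border, tag, tile, offset) {
  list(image = image, blob = blob, border = border, tag = tag,
       tile = tile, offset = as.integer(offset))
}

.cropPatchFromTile <- function(tile, border, r0, c0, tag) {
  # r0, c0 are 0-based offsets
  rows <- r0 + seq_len(200L)
  cols <- c0 + seq_len(200L)
  mask <- tileMask(tile)
  .newSegPatch(tileImage(tile)[rows, cols, , drop = FALSE],
               matrix(as.numeric(mask[rows, cols] > 0L), 200L, 200L),
               matrix(as.numeric(border[rows, cols]), 200L, 200L),
               tag, tileId(tile), c(r0, c0))
}

# Stable per-tile RNG substream so the content of a tile's random crops does
# not depend on the order tiles are processed in.
.tileSeed <- function(seed, id) {
  h <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id))) %% 65536L
  (as.integer(seed) %% 32768L) * 65536L + h
}

#' Extract the nuclei-blob (NBL) patch set from a tile
#'
#' Slides a 200x200 window at multiples of \code{step} (all positions where
#' the window fits), then adds \code{nRandom} uniformly random window offsets.
#'
#' @param tile a \code{\link{NucleiTile}} with a labeled mask, at least
#'   200x200.
#' @param step sliding-window step in pixels.
#' @param nRandom number of additional random crops.
#' @param seed RNG seed (a per-tile substream is derived from it).
#' @param borderThickness border-target thickness passed to
#'   \code{\link{makeBorderTarget}}.
#' @return list of segmentation patches tagged \code{"NBL"}.
#' @export
extractNBL <- function(tile, step = 54L, nRandom = 30L, seed = 1L,
                       borderThickness = 2L) {
  d <- dim(tileImage(tile))
  if (d[1] < 200L || d[2] < 200L) stop("tile smaller than 200 x 200")
  if (is.null(tileMask(tile))) stop("tile has no labeled mask")
  border <- makeBorderTarget(tileMask(tile), borderThickness)
  rOff <- seq.int(0L, d[1] - 200L, by = step)
  cOff <- seq.int(0L, d[2] - 200L, by = step)
  patches <- list()
  for (r0 in rOff)
    for (c0 in cOff)
      patches[[length(patches) + 1L]] <-
        .cropPatchFromTile(tile, border, r0, c0, "NBL")
  withSeed(.tileSeed(seed, tileId(tile)), {
    for (k in seq_len(nRandom)) {
      r0 <- sample.int(d[1] - 200L + 1L, 1L) - 1L
      c0 <- sample.int(d[2] - 200L + 1L, 1L) - 1L
      patches[[length(patches) + 1L]] <-
        .cropPatchFromTile(tile, border, r0, c0, "NBL")
    }
  })
  patches
}

#' Extract the nuclei-boundary (NBD) patch set from a tile
#'
#' One 200x200 patch per nucleus, centered on the nucleus centroid (rounded
#' down); nuclei whose centroid lies within 100 px of a tile edge are ignored
#' so the patch fits without padding.
#'
#' @inheritParams extractNBL
#' @return list of segmentation patches tagged \code{"NBD"}.
#' @export
extractNBD <- function(tile, borderThickness = 2L) {
  mask <- tileMask(tile)
  if (is.null(mask)) stop("tile has no labeled mask")
  d <- dim(mask)
  border <- makeBorderTarget(mask, borderThickness)
  ids <- sort(unique(mask[mask > 0L]))
  patches <- list()
  for (id in ids) {
    px <- which(mask == id, arr.ind = TRUE)
    cr <- floor(mean(px[, 1] - 1))  # 0-based centroid
    cc <- floor(mean(px[, 2] - 1))
    if (cr < 100L || cr > d[1] - 101L || cc < 100L || cc > d[2] - 101L)
      next
    patches[[length(patches) + 1L]] <-
      .cropPatchFromTile(tile, border, cr - 100L, cc - 100L, "NBD")
  }
  patches
}

#' Duplicate sparse NBL patches into the small-nuclei (SN) set
#'
#' Patches whose nucleus-pixel fraction inside the centered
#' \code{centerSide} x \code{centerSide} window is at most \code{maxFraction}
#' (inclusive) are duplicated \code{copies} times and tagged \code{"SN"};
#' each copy's image equals its source byte for byte.
#'
#' @param nblPatches list of patches tagged \code{"NBL"}.
#' @param centerSide side of the central window (default 54).
#' @param maxFraction inclusive upper bound on the nucleus-pixel fraction.
#' @param copies duplicates per qualifying patch.
#' @return list of patches tagged \code{"SN"}.
#' @export
extractSN <- function(nblPatches, centerSide = 54L, maxFraction = 0.5,
                      copies = 3L) {
  out <- list()
  for (p in nblPatches) {
    if (!identical(p$tag, "NBL")) stop("extractSN expects NBL patches")
    frac <- mean(centerCrop(p$blob, centerSide))
    if (frac <= maxFraction) {
      q <- p
      q$tag <- "SN"
      for (k in seq_len(copies)) out[[length(out) + 1L]] <- q
    }
  }
  out
}

#' Border ground truth from a labeled mask
#'
#' Marks the pixels of each object that touch (8-adjacency) background or a
#' different id — including the shared interface of touching nuclei — and
#' thickens the resulting outline to \code{thickness} pixels into the
#' objects (a box dilation of the outline intersected with the foreground).
#'
#' @param mask integer labeled mask.
#' @param thickness border thickness in pixels (>= 1).
#' @return binary matrix of border pixels.
#' @export
makeBorderTarget <- function(mask, thickness = 2L) {
  H <- nrow(mask); W <- ncol(mask)
  if (H == 0L || W == 0L) return(matrix(0, H, W))
  pad <- matrix(-1L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  ctr <- pad[2:(H + 1L), 2:(W + 1L)]
  boundary <- matrix(FALSE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[2:(H + 1L) + dr, 2:(W + 1L) + dc]
    boundary <- boundary | (ctr > 0L & nb != ctr)
  }
  out <- boundary
  if (thickness > 1L)
    out <- dilateBox3(boundary, iter = thickness - 1L) & ctr > 0L
  matrix(as.numeric(out), H, W)
}

#' Augmentation parameter set
#'
#' Random shift, rotation, axis flips, shear and rescaling applied jointly to
#' a patch image and its targets; three augmented copies per patch by
#' default.
#'
#' @param shiftRange vertical/horizontal shift as a fraction of the patch
#'   side.
#' @param rotationRange rotation in degrees.
#' @param flipProb probability of a flip along each axis.
#' @param shearRange shear intensity in radians.
#' @param resizeRange rescaling ratio range.
#' @param repeats augmented copies per patch in \code{\link{augmentDataset}}.
#' @return list of class \code{"AugmentParams"}.
#' @export
augmentParams <- function(shiftRange = c(-0.05, 0.05),
                          rotationRange = c(-45, 45), flipProb = 0.5,
                          shearRange = c(-0.4 * pi, 0.4 * pi),
                          resizeRange = c(0.6, 2.0), repeats = 3L) {
  structure(list(shiftRange = shiftRange, rotationRange = rotationRange,
                 flipProb = flipProb, shearRange = shearRange,
                 resizeRange = resizeRange, repeats = as.integer(repeats)),
            class = "AugmentParams")
}

# Compose the inverse affine map (output pixel -> source pixel, 0-based
# row/col) for a draw about the patch center.
.augmentInverseMap <- function(side, draw) {
  ctr <- (side - 1) / 2
  th <- draw$rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Sh <- matrix(c(1, 0, -sin(draw$shear), cos(draw$shear)), 2, 2)
  Fl <- diag(c(if (draw$flipV) -1 else 1, if (draw$flipH) -1 else 1))
  A <- R %*% Sh %*% Fl * draw$scale
  Ainv <- solve(A)
  shift <- c(draw$shift[1], draw$shift[2]) * side
  # forward: y = A (x - ctr) + ctr + shift  =>  x = Ainv (y - ctr - shift) + ctr
  off <- -Ainv %*% (c(ctr, ctr) + shift) + c(ctr, ctr)
  cbind(Ainv, off)
}

#' Augment one segmentation patch
#'
#' Draws a random shift / rotation / flip / shear / rescale and applies the
#' identical geometric transform to the image (bilinear) and both targets
#' (nearest neighbor, so the target alphabet stays binary). Samples falling
#' outside the source after transformation are filled by mirror reflection.
#'
#' @param patch a segmentation patch.
#' @param params an \code{\link{augmentParams}} object.
#' @param seed optional RNG seed for the draw.
#' @param draw optional explicit draw (list with \code{shift} length-2
#'   fraction, \code{rotation} degrees, \code{flipV}, \code{flipH},
#'   \code{shear}, \code{scale}) bypassing the random draw.
#' @return the augmented patch (same size).
#' @export
augmentPatch <- function(patch, params = augmentParams(), seed = NULL,
                         draw = NULL) {
  d <- dim(patch$image)
  if (d[1] != d[2]) stop("expected a square patch")
  if (is.null(draw))
    draw <- withSeed(seed, list(
      shift = runif(2, params$shiftRange[1], params$shiftRange[2]),
      rotation = runif(1, params$rotationRange[1], params$rotationRange[2]),
      flipV = runif(1) < params$flipProb,
      flipH = runif(1) < params$flipProb,
      shear = runif(1, params$shearRange[1], params$shearRange[2]),
      scale = runif(1, params$resizeRange[1], params$resizeRange[2])))
  M <- .augmentInverseMap(d[1], draw)
  img <- .affine_sample(patch$image, M, d[1], d[2], TRUE)
  asTarget <- function(m) {
    a <- array(m, c(d[1], d[2], 1L))
    matrix(.affine_sample(a, M, d[1], d[2], FALSE), d[1], d[2])
  }
  patch$image <- img
  patch$blob <- asTarget(patch$blob)
  patch$border <- asTarget(patch$border)
  patch
}

#' Augment a patch set
#'
#' Produces \code{params$repeats} augmented copies of every patch,
#' deterministically under \code{seed}.
#'
#' @param patches list of segmentation patches.
#' @param params an \code{\link{augmentParams}}.
#' @param seed RNG seed.
#' @return list of augmented patches (length \code{repeats * length(patches)}).
#' @export
augmentDataset <- function(patches, params = augmentParams(), seed = 1L) {
  out <- vector("list", length(patches) * params$repeats)
  k <- 0L
  withSeed(seed, {
    for (p in patches)
      for (r in seq_len(params$repeats)) {
        k <- k + 1L
        out[[k]] <- augmentPatch(p, params)
      }
  })
  out
}

#' Center crop of an image, target or feature array
#'
#' Crops the centered \code{side} x \code{side} window (offset
#' \code{floor((n - side) / 2)} per axis): 200 -> 102 for network input.
#'
#' @param x matrix or (H, W, C) array, both sides >= \code{side}.
#' @param side crop side in pixels.
#' @return the cropped matrix/array.
#' @export
centerCrop <- function(x, side = 102L) {
  d <- dim(x)
  if (d[1] < side || d[2] < side) stop("input smaller than crop side")
  r0 <- (d[1] - side) %/% 2
  c0 <- (d[2] - side) %/% 2
  if (length(d) == 2L) x[r0 + seq_len(side), c0 + seq_len(side), drop = FALSE]
  else x[r0 + seq_len(side), c0 + seq_len(side), , drop = FALSE]
}

#' @rdname centerCrop
#' @details \code{targetCrop} is the training-target counterpart (200 -> 54,
#'   aligned with the center of the 102 network input).
#' @export
targetCrop <- function(x, side = 54L) centerCrop(x, side)
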