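#' @include engine.R seg_data.R
NULL

#' Tile inference configuration
#'
#' @param inputSide network input window (102).
#' @param outputSide network output window (54).
#' @param blobThreshold,borderThreshold probability thresholds (inclusive:
#'   probability equal to the threshold is foreground).
#' @param minAreaUm2 minimum object area in square microns; smaller objects
#'   are removed as artifacts.
#' @return list of class \code{"InferenceConfig"}. The reflection pad is
#'   \code{(inputSide - outputSide) / 2} and the stitch stride equals the
#'   output side, so the 54x54 outputs tile the image exactly.
#' @export
inferenceConfig <- function(inputSide = 102L, outputSide = 54L,
                            blobThreshold = 0.5, borderThreshold = 0.5,
                            minAreaUm2 = 13) {
  if ((inputSide - outputSide) %% 2L != 0L)
    stop("inputSide - outputSide must be even")
  stopifnotScalarIn01(blobThreshold, "blobThreshold")
  stopifnotScalarIn01(borderThreshold, "borderThreshold")
  structure(list(inputSide = as.integer(inputSide),
                 outputSide = as.integer(outputSide),
                 pad = as.integer((inputSide - outputSide) %/% 2L),
                 blobThreshold = blobThreshold,
                 borderThreshold = borderThreshold,
                 minAreaUm2 = minAreaUm2),
            class = "InferenceConfig")
}

#' 8- or 4-connected component labeling
#'
#' Labels connected sets of equal-valued nonzero cells in scan order.
#'
#' @param mask integer (or logical) matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer label matrix with ids 1..n.
#' @export
labelConnected <- function(mask, connectivity = 8L) {
  m <- mask
  if (!is.integer(m)) {
    m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  }
  .label_connected(m, as.integer(connectivity))
}

#' Sliding-window probability map and foreground mask for a tile
#'
#' Reflection-pads the tile by \code{(input - output) / 2}, forwards 102x102
#' windows at stride 54 (with extra right/bottom reflection so the abutting
#' 54x54 outputs cover the tile), stitches the foreground-probability map and
#' thresholds it (inclusive).
#'
#' @param net a \code{\link{TrainedNetwork}} (blob or border DRAN/MDRAN).
#' @param tile a \code{\link{NucleiTile}} or an (H, W, 3) array.
#' @param config an \code{\link{inferenceConfig}}.
#' @param threshold probability threshold; defaults to the blob threshold.
#' @param batchSize windows forwarded per batch.
#' @return list with \code{prob} (H x W foreground probabilities) and
#'   \code{mask} (binary matrix).
#' @export
predictMask <- function(net, tile, config = inferenceConfig(),
                        threshold = config$blobThreshold, batchSize = 8L) {
  img <- if (is(tile, "NucleiTile")) tileImage(tile) else tile
  H <- dim(img)[1]; W <- dim(img)[2]
  outS <- config$outputSide
  inS <- config$inputSide
  pad <- config$pad
  nr <- ceiling(H / outS)
  nc <- ceiling(W / outS)
  # pad so that every 102-window at stride 54 fits
  needH <- (nr - 1L) * outS + inS
  needW <- (nc - 1L) * outS + inS
  # pad by `pad` at top/left and enough at bottom/right: reflect generously,
  # then re-anchor so index 1 corresponds to image row/col 1 - pad
  padded <- reflectPad(img, pad + outS)
  padded <- padded[outS + seq_len(needH), outS + seq_len(needW), ,
                   drop = FALSE]
  prob <- matrix(0, nr * outS, nc * outS)
  cells <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  for (b0 in seq.int(1L, nrow(cells), by = batchSize)) {
    bi <- b0:min(b0 + batchSize - 1L, nrow(cells))
    x <- array(0, c(inS, inS, 3, length(bi)))
    for (k in seq_along(bi)) {
      r0 <- (cells$r[bi[k]] - 1L) * outS
      c0 <- (cells$c[bi[k]] - 1L) * outS
      x[, , , k] <- padded[r0 + seq_len(inS), c0 + seq_len(inS), ]
    }
    y <- forwardNetwork(net, x)  # (54, 54, 2, n)
    for (k in seq_along(bi)) {
      r0 <- (cells$r[bi[k]] - 1L) * outS
      c0 <- (cells$c[bi[k]] - 1L) * outS
      prob[r0 + seq_len(outS), c0 + seq_len(outS)] <- y[, , 2L, k]
    }
  }
  prob <- prob[seq_len(H), seq_len(W), drop = FALSE]
  list(prob = prob, mask = matrix(as.numeric(prob >= threshold), H, W))
}

#' Separate touching nuclei from blob and border masks
#'
#' The paper's initial-segmentation recipe: dilate the border mask with a
#' 3x3 kernel and subtract it from the blob mask to expose nucleus cores;
#' label the cores (8-connected); then assign every removed blob pixel to its
#' geodesically nearest core by a marker-controlled watershed over the blob
#' support. Blob components whose core is entirely erased by the dilated
#' border fall back to the whole component as their own marker, so
#' detections are never silently deleted. The result is a partition of the
#' blob foreground.
#'
#' @param blob,border binary matrices of identical dimension.
#' @param config an \code{\link{inferenceConfig}} (kept for interface
#'   symmetry; the kernel is fixed at 3x3).
#' @return integer labeled mask.
#' @export
separateNuclei <- function(blob, border, config = inferenceConfig()) {
  if (!identical(dim(blob), dim(border)))
    stop("blob and border masks must have identical dimensions")
  blobL <- blob != 0
  if (!any(blobL)) return(matrix(0L, nrow(blob), ncol(blob)))
  borderD <- dilateBox3(border, iter = 1L)
  cores <- blobL & !borderD
  markers <- labelConnected(cores, 8L)
  nCores <- max(markers)
  # fallback: blob components left with no core become their own marker
  comps <- labelConnected(blobL, 8L)
  for (cid in seq_len(max(comps))) {
    sel <- comps == cid
    if (!any(markers[sel] > 0L)) {
      nCores <- nCores + 1L
      markers[sel] <- nCores
    }
  }
  .geodesic_label(matrix(as.integer(blobL), nrow(blob)), markers)
}

#' Remove objects below a physical area threshold
#'
#' Objects smaller than \code{minAreaUm2 / mpp^2} pixels are eliminated as
#' artifacts (13 um^2 is below any real nucleus); objects exactly at the
#' pixel threshold survive. Surviving ids are compacted to 1..n preserving
#' order.
#'
#' @param labels integer labeled mask.
#' @param minAreaUm2 area threshold in square microns.
#' @param mpp microns per pixel (> 0).
#' @return filtered labeled mask.
#' @export
areaFilter <- function(labels, minAreaUm2 = 13, mpp = 0.25) {
  if (mpp <= 0) stop("mpp must be positive")
  thresholdPx <- minAreaUm2 / mpp^2
  sizes <- table(labels[labels > 0L])
  keep <- as.integer(names(sizes)[sizes >= thresholdPx])
  out <- matrix(0L, nrow(labels), ncol(labels))
  newId <- 0L
  for (id in sort(keep)) {
    newId <- newId + 1L
    out[labels == id] <- newId
  }
  out
}

#' Full tile segmentation
#'
#' predict (blob + border probability maps) -> separate (border subtraction
#' and watershed) -> filter (physical area). Deterministic given weights and
#' tile. Pass \code{oracle} to substitute ground-truth blob/border masks for
#' the networks (post-processing test mode).
#'
#' @param blobNet,borderNet \code{\link{TrainedNetwork}}s (ignored when
#'   \code{oracle} is given).
#' @param tile a \code{\link{NucleiTile}}.
#' @param config an \code{\link{inferenceConfig}}.
#' @param oracle optional list with binary matrices \code{blob} and
#'   \code{border}.
#' @return integer labeled mask of segmented nuclei.
#' @export
segmentTile <- function(blobNet, borderNet, tile,
                        config = inferenceConfig(), oracle = NULL) {
  if (is.null(oracle)) {
    blob <- predictMask(blobNet, tile, config, config$blobThreshold)$mask
    border <- predictMask(borderNet, tile, config,
                          config$borderThreshold)$mask
  } else {
    blob <- oracle$blob
    border <- oracle$border
  }
  labels <- separateNuclei(blob, border, config)
  areaFilter(labels, config$minAreaUm2,
             if (is(tile, "NucleiTile")) tileMpp(tile) else 0.25)
}

# Brute-force Euclidean nearest-core assignment (independent oracle for the
# geodesic watershed on simply-connected supports). Internal; used by tests.
.euclideanNearestCore <- function(blob, markers) {
  out <- matrix(0L, nrow(blob), ncol(blob))
  fg <- which(blob != 0, arr.ind = TRUE)
  mk <- which(markers > 0L, arr.ind = TRUE)
  if (nrow(mk) == 0L) return(out)
  ids <- markers[mk]
  for (k in seq_len(nrow(fg))) {
    d2 <- (fg[k, 1] - mk[, 1])^2 + (fg[k, 2] - mk[, 2])^2
    best <- which(d2 == min(d2))
    out[fg[k, 1], fg[k, 2]] <- min(ids[best])
  }
  out
}
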