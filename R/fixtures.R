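#' @include utils.R AllGenerics.R
NULL

#' Specification of a synthetic H&E tile
#'
#' Describes a synthetic hematoxylin-and-eosin-like tissue tile: dark-purple
#' elliptical nuclei on a pink background with Gaussian noise, a controllable
#' fraction of nuclei placed as touching pairs, and an exact labeled instance
#' mask. Contested pixels of a touching pair belong to the later-placed
#' nucleus, so the mask is a partition.
#'
#' @param width,height tile size in pixels (>= 200).
#' @param nNuclei number of nuclei.
#' @param radiusRange (min, max) semi-major axis in pixels (min >= 3). The
#'   default 11-18 px corresponds to nucleus diameters of roughly 5.5-9
#'   microns at 40x (0.25 microns per pixel), comfortably above the 13 um^2
#'   artifact-filter threshold.
#' @param touchingFraction fraction of nuclei placed as touching pairs.
#' @param overlapPx pixels of overlap along the center line of a touching
#'   pair (>= 1 so the pair is 8-adjacent; keep small so each nucleus keeps
#'   interior pixels).
#' @param stainNucleus,stainBackground mean RGB triplets in \code{[0, 1]}.
#' @param stainSd per-nucleus RGB jitter standard deviation.
#' @param noiseSd per-pixel Gaussian noise standard deviation.
#' @param seed integer seed; the generator is a pure function of spec + seed.
#' @return a validated spec list of class \code{"SyntheticTileSpec"}.
#' @export
syntheticTileSpec <- function(width = 400L, height = 400L, nNuclei = 20L,
                              radiusRange = c(11, 18),
                              touchingFraction = 0.2, overlapPx = 2L,
                              stainNucleus = c(0.36, 0.22, 0.51),
                              stainBackground = c(0.91, 0.74, 0.83),
                              stainSd = 0.03, noiseSd = 0.03, seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               nNuclei = as.integer(nNuclei), radiusRange = radiusRange,
               touchingFraction = touchingFraction,
               overlapPx = as.integer(overlapPx),
               stainNucleus = stainNucleus,
               stainBackground = stainBackground,
               stainSd = stainSd, noiseSd = noiseSd, seed = as.integer(seed))
  if (spec$width < 200L || spec$height < 200L)
    stop("tile must be at least 200 x 200")
  if (spec$radiusRange[1] < 3) stop("minimum radius must be >= 3")
  if (spec$nNuclei < 0L) stop("nNuclei must be non-negative")
  stopifnotScalarIn01(spec$touchingFraction, "touchingFraction")
  if (spec$overlapPx < 1L || spec$overlapPx > spec$radiusRange[1] - 2L)
    stop("overlapPx must be in [1, min radius - 2]")
  class(spec) <- "SyntheticTileSpec"
  spec
}

# Radius of an ellipse (semi-axes a, b, orientation theta) along direction phi.
.ellipseRadius <- function(a, b, theta, phi) {
  ct <- cos(phi - theta) / a
  st <- sin(phi - theta) / b
  1 / sqrt(ct^2 + st^2)
}

# Rasterize an ellipse into row/col index vectors (1-based, clipped).
.ellipsePixels <- function(cy, cx, a, b, theta, H, W) {
  r0 <- max(1L, floor(cy - a)); r1 <- min(H, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(W, ceiling(cx + a))
  if (r0 > r1 || c0 > c1) return(cbind(integer(0), integer(0)))
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  dy <- rr - cy; dx <- cc - cx
  u <- (dy * cos(theta) + dx * sin(theta)) / a
  v <- (-dy * sin(theta) + dx * cos(theta)) / b
  keep <- u^2 + v^2 <= 1
  cbind(rr[keep], cc[keep])
}

#' Generate a synthetic H&E tile with an exact labeled mask
#'
#' Places elliptical nuclei (random orientation and eccentricity) by rejection
#' sampling: touching pairs share a stated overlap along their center line so
#' the two ids are 8-adjacent; all other nuclei keep a clear margin from each
#' other. Mask ids are contiguous 1..n in placement order. Identical spec
#' (including seed) reproduces bit-identical output.
#'
#' @param spec a \code{\link{syntheticTileSpec}}.
#' @param maxTries placement retries per nucleus before giving up.
#' @return a \code{\link{NucleiTile}} (image plus labeled mask).
#' @export
generateNucleiTile <- function(spec, maxTries = 200L) {
  stopifnot(inherits(spec, "SyntheticTileSpec"))
  H <- spec$height; W <- spec$width
  withSeed(spec$seed, {
    mask <- matrix(0L, H, W)
    nPairs <- ceiling(spec$touchingFraction * spec$nNuclei / 2)
    nPairs <- min(nPairs, spec$nNuclei %/% 2L)
    placed <- list()  # cy, cx, a (bounding radius)
    rmin <- spec$radiusRange[1]; rmax <- spec$radiusRange[2]
    margin <- 3
    drawShape <- function() {
      a <- runif(1, rmin, rmax)
      list(a = a, b = a * runif(1, 0.6, 1), theta = runif(1, 0, pi))
    }
    farFromAll <- function(cy, cx, a, skip = 0L) {
      for (p in placed[setdiff(seq_along(placed), skip)])
        if (sqrt((cy - p$cy)^2 + (cx - p$cx)^2) < a + p$a + margin)
          return(FALSE)
      TRUE
    }
    placeOne <- function(shape) {
      for (t in seq_len(maxTries)) {
        cy <- runif(1, shape$a + 2, H - shape$a - 1)
        cx <- runif(1, shape$a + 2, W - shape$a - 1)
        if (farFromAll(cy, cx, shape$a)) return(c(cy, cx))
      }
      NULL
    }
    nextId <- 0L
    stamp <- function(cy, cx, shape) {
      nextId <<- nextId + 1L
      px <- .ellipsePixels(cy, cx, shape$a, shape$b, shape$theta, H, W)
      mask[px] <<- nextId
      placed[[nextId]] <<- list(cy = cy, cx = cx, a = shape$a)
    }
    # touching pairs first
    for (k in seq_len(nPairs)) {
      ok <- FALSE
      for (t in seq_len(maxTries)) {
        s1 <- drawShape(); s2 <- drawShape()
        phi <- runif(1, 0, 2 * pi)
        d <- .ellipseRadius(s1$a, s1$b, s1$theta, phi) +
          .ellipseRadius(s2$a, s2$b, s2$theta, phi + pi) - spec$overlapPx
        cy1 <- runif(1, s1$a + s2$a + 4, H - s1$a - s2$a - 3)
        cx1 <- runif(1, s1$a + s2$a + 4, W - s1$a - s2$a - 3)
        cy2 <- cy1 + d * cos(phi); cx2 <- cx1 + d * sin(phi)
        inside2 <- cy2 > s2$a + 2 && cy2 < H - s2$a - 1 &&
          cx2 > s2$a + 2 && cx2 < W - s2$a - 1
        if (inside2 && farFromAll(cy1, cx1, s1$a + s2$a + d)) {
          stamp(cy1, cx1, s1)
          stamp(cy2, cx2, s2)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("placement failure: could not place touching pair ", k)
    }
    # singles, kept non-adjacent to everything
    for (k in seq_len(spec$nNuclei - 2L * nPairs)) {
      shape <- drawShape()
      pos <- placeOne(shape)
      if (is.null(pos))
        stop("placement failure: could not place nucleus ",
             2L * nPairs + k)
      stamp(pos[1], pos[2], shape)
    }
    # every id must own at least one pixel (overlap can only shave the
    # earlier pair member's rim, never its interior, by construction)
    ids <- sort(unique(mask[mask > 0L]))
    if (spec$nNuclei > 0L && !identical(ids, seq_len(spec$nNuclei)))
      stop("placement failure: lost a nucleus id")
    # render: pink background, dark-purple nuclei, per-nucleus stain jitter
    img <- array(rep(spec$stainBackground, each = H * W), c(H, W, 3))
    if (spec$nNuclei > 0L) {
      jitter <- matrix(rnorm(3L * spec$nNuclei, 0, spec$stainSd),
                       spec$nNuclei, 3L)
      for (ch in 1:3) {
        plane <- img[, , ch]
        sel <- mask > 0L
        plane[sel] <- spec$stainNucleus[ch] + jitter[mask[sel], ch]
        img[, , ch] <- plane
      }
    }
    img <- clamp01(img + array(rnorm(length(img), 0, spec$noiseSd), dim(img)))
    NucleiTile(img, mask, magnification = "40x",
               id = sprintf("synth-%d", spec$seed))
  })
}

#' Canonical split / merge fixture masks
#'
#' Builds a reference/prediction mask pair over the same pixel support: with
#' \code{mode = "split"} the reference holds one object and the prediction
#' covers it with two equal halves (the classic over-segmentation the
#' object-level Dice penalizes); \code{"merge"} is the transpose;
#' \code{"identical"} returns two equal one-object masks.
#'
#' @param mode \code{"identical"}, \code{"split"} or \code{"merge"}.
#' @param objectPx object size in pixels (even for split/merge).
#' @return list with integer matrices \code{reference} and \code{prediction}.
#' @export
generateSplitMergeCase <- function(mode = c("identical", "split", "merge"),
                                   objectPx = 208L) {
  mode <- match.arg(mode)
  objectPx <- as.integer(objectPx)
  if (mode != "identical" && objectPx %% 2L != 0L)
    stop("objectPx must be even for split/merge")
  rows <- 8L
  cols <- as.integer(ceiling(objectPx / rows))
  if (rows * cols != objectPx) {
    rows <- 1L
    cols <- objectPx
  }
  H <- rows + 4L
  W <- cols + 4L
  one <- matrix(0L, H, W)
  one[2L + seq_len(rows), 2L + seq_len(cols)] <- 1L
  two <- matrix(0L, H, W)
  two[2L + seq_len(rows), 2L + seq_len(cols %/% 2L)] <- 1L
  two[2L + seq_len(rows), 2L + cols %/% 2L + seq_len(cols - cols %/% 2L)] <- 2L
  switch(mode,
    identical = list(reference = one, prediction = one),
    split = list(reference = one, prediction = two),
    merge = list(reference = two, prediction = one))
}

#' Generate synthetic per-slide class probability maps
#'
#' Each grid cell receives a 3-class probability vector. With probability
#' \code{effect} the cell is dominant-forced (the dominant class receives
#' probability 0.6-1.0); otherwise the vector is uniform-Dirichlet. The
#' expected fraction of cells whose argmax is the dominant class is therefore
#' \code{effect + (1 - effect) / 3}, increasing monotonically in
#' \code{effect}; at 0 the argmax frequencies are uniform and at 1 every cell
#' votes the dominant class.
#'
#' @param gridH,gridW patch-grid size in cells.
#' @param dominantClass \code{"LUAD"}, \code{"LUSC"} or \code{"ND"}.
#' @param effect class separation in \code{[0, 1]}.
#' @param seed integer seed.
#' @return a \code{\link{ProbabilityMaps}}.
#' @export
generateProbabilityMaps <- function(gridH, gridW,
                                    dominantClass = c("LUAD", "LUSC", "ND"),
                                    effect = 0.8, seed = 1L) {
  dominantClass <- match.arg(dominantClass)
  stopifnotScalarIn01(effect, "effect")
  n <- gridH * gridW
  withSeed(seed, {
    p <- matrix(rexp(3L * n), n, 3L)  # uniform Dirichlet after normalization
    p <- p / rowSums(p)
    forced <- runif(n) < effect
    di <- match(dominantClass, c("ND", "LUAD", "LUSC"))
    if (any(forced)) {
      nf <- sum(forced)
      pd <- 0.6 + 0.4 * runif(nf)
      rest <- matrix(rexp(2L * nf), nf, 2L)
      rest <- rest / rowSums(rest) * (1 - pd)
      pf <- matrix(0, nf, 3L)
      pf[, di] <- pd
      pf[, -di] <- rest
      p[forced, ] <- pf
    }
    ProbabilityMaps(nd = matrix(p[, 1L], gridH, gridW),
                    luad = matrix(p[, 2L], gridH, gridW),
                    lusc = matrix(p[, 3L], gridH, gridW))
  })
}

# Render one synthetic 256x256 patch for a patch class. Diagnostic classes
# differ in base color and blob texture; ND is pale background-like tissue.
.renderClsPatch <- function(cls, strength = 1) {
  side <- 256L
  base <- switch(cls,
    LUAD = c(0.60, 0.40, 0.65),
    LUSC = c(0.85, 0.55, 0.60),
    ND = c(0.92, 0.88, 0.90))
  mid <- c(0.79, 0.61, 0.72)
  col <- mid + strength * (base - mid)
  img <- array(rep(col, each = side * side), c(side, side, 3))
  nBlobs <- switch(cls, LUAD = 60L, LUSC = 25L, ND = 8L)
  blobCol <- switch(cls,
    LUAD = c(0.30, 0.18, 0.45), LUSC = c(0.55, 0.30, 0.45),
    ND = c(0.80, 0.75, 0.80))
  for (k in seq_len(nBlobs)) {
    cy <- runif(1, 8, side - 8)
    cx <- runif(1, 8, side - 8)
    a <- runif(1, 3, if (cls == "LUSC") 14 else 7)
    px <- .ellipsePixels(cy, cx, a, a * runif(1, 0.4, 1),
                         runif(1, 0, pi), side, side)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[px] <- blobCol[ch]
      img[, , ch] <- plane
    }
  }
  clamp01(img + array(rnorm(length(img), 0, 0.04), dim(img)))
}

#' Generate labeled classification patch grids for synthetic slides
#'
#' Emits balanced LUAD/LUSC slide labels (alternating) and, per slide, a grid
#' of 256x256 RGB patches whose color/texture depends on the patch class;
#' a fraction of cells per slide are non-diagnostic (ND) tissue, the rest
#' carry the slide's class. Patch-level labels are returned alongside grid
#' coordinates (0-based row/col of a non-overlapping tiling).
#'
#' @param nSlides number of slides (labels alternate LUAD/LUSC).
#' @param patchesPerSlide patches per slide (laid out on a near-square grid).
#' @param seed integer seed.
#' @param effect class-separation strength in \code{[0, 1]} scaling the color
#'   margin between classes.
#' @param ndFraction expected fraction of ND cells per slide.
#' @return list with \code{patches} (list of records: \code{image},
#'   \code{label}, \code{slide}, \code{row}, \code{col}) and \code{slides}
#'   (data.frame of slide ids and labels).
#' @export
generateClassificationPatches <- function(nSlides, patchesPerSlide, seed = 1L,
                                          effect = 0.9, ndFraction = 0.25) {
  if (nSlides < 1L || patchesPerSlide < 1L) stop("counts must be >= 1")
  stopifnotScalarIn01(effect, "effect")
  slideLabels <- rep(c("LUAD", "LUSC"), length.out = nSlides)
  slideIds <- sprintf("slide%02d", seq_len(nSlides))
  gw <- ceiling(sqrt(patchesPerSlide))
  withSeed(seed, {
    patches <- list()
    for (s in seq_len(nSlides)) {
      for (k in seq_len(patchesPerSlide)) {
        isND <- runif(1) < ndFraction
        cls <- if (isND) "ND" else slideLabels[s]
        patches[[length(patches) + 1L]] <- list(
          image = .renderClsPatch(cls, strength = effect),
          label = cls, slide = slideIds[s],
          row = (k - 1L) %/% gw, col = (k - 1L) %% gw)
      }
    }
    list(patches = patches,
         slides = data.frame(slide = slideIds, label = slideLabels,
                             stringsAsFactors = FALSE))
  })
}
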