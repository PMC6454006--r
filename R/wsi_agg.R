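#' @include AllGenerics.R seg_pipeline.R
NULL

#' Assemble per-slide probability maps from patch predictions
#'
#' Places each patch's class probability triple at its (row, col) grid cell;
#' grid extents come from the maximal indices; cells without a prediction are
#' filled as pure non-diagnostic (1, 0, 0). Input order is irrelevant;
#' duplicate coordinates are an error.
#'
#' @param predictions data.frame with columns \code{row}, \code{col}
#'   (0-based patch-grid coordinates) and \code{p_nd}, \code{p_luad},
#'   \code{p_lusc}.
#' @return a \code{\link{ProbabilityMaps}}.
#' @export
assembleProbabilityMaps <- function(predictions) {
  need <- c("row", "col", "p_nd", "p_luad", "p_lusc")
  if (!all(need %in% names(predictions)))
    stop("predictions must have columns ", paste(need, collapse = ", "))
  key <- paste(predictions$row, predictions$col)
  if (anyDuplicated(key)) stop("duplicate patch-grid coordinate")
  H <- max(predictions$row) + 1L
  W <- max(predictions$col) + 1L
  nd <- matrix(1, H, W)
  luad <- matrix(0, H, W)
  lusc <- matrix(0, H, W)
  idx <- cbind(predictions$row + 1L, predictions$col + 1L)
  nd[idx] <- predictions$p_nd
  luad[idx] <- predictions$p_luad
  lusc[idx] <- predictions$p_lusc
  ProbabilityMaps(nd, luad, lusc)
}

.featThresholds <- c(0.5, 0.7, 0.9)
.ratioEps <- 1e-6

# Sizes (cells, descending, zero-padded to 5) of the largest components of
# map >= tau under 8-connectivity.
.topComponents <- function(map, tau, k = 5L) {
  bin <- map >= tau
  if (!any(bin)) return(numeric(k))
  lab <- labelConnected(bin, 8L)
  sizes <- sort(as.integer(table(lab[lab > 0L])), decreasing = TRUE)
  out <- numeric(k)
  out[seq_len(min(k, length(sizes)))] <- head(sizes, k)
  out
}

#' Names of the 50 probability-map features
#'
#' @return character vector of length 50 in canonical order (the tie-break
#'   order of \code{\link{selectFeatures}}).
#' @export
featureNames <- function() {
  perMap <- function(m) c(
    sprintf("%s_mean", m), sprintf("%s_median", m), sprintf("%s_var", m),
    sprintf("%s_pos_count_t50", m), sprintf("%s_pos_frac_t50", m),
    as.vector(t(outer(c(50, 70, 90), 1:5,
                      function(t, i) sprintf("%s_cc%d_t%d", m, i, t)))))
  c(perMap("luad"), perMap("lusc"),
    "ratio_mean", "ratio_median", "ratio_var", "ratio_mass",
    sprintf("ratio_pos_t%d", c(50, 70, 90)),
    sprintf("ratio_cc1_t%d", c(50, 70, 90)))
}

#' Extract the 50 statistical and morphological map features
#'
#' From the LUAD and LUSC probability maps of one slide: per map the mean,
#' median and (population) variance; the positive-cell count and fraction at
#' threshold 0.5; and the sizes of the five largest 8-connected components
#' at thresholds 0.5 / 0.7 / 0.9 (descending, zero-padded). Plus ten
#' LUAD:LUSC ratio features (epsilon-guarded, so two all-zero maps give
#' ratio 1): mean, median, variance and total-mass ratios, positive-count
#' ratios and largest-component ratios at the three thresholds.
#'
#' @param maps a \code{\link{ProbabilityMaps}}.
#' @return named numeric vector of length 50.
#' @export
extractFeatures <- function(maps) {
  if (length(maps@luad) == 0L) stop("empty probability maps")
  popVar <- function(x) mean((x - mean(x))^2)
  perMap <- function(m) {
    cc <- unlist(lapply(.featThresholds, function(t) .topComponents(m, t)))
    c(mean(m), median(m), popVar(m), sum(m >= 0.5), mean(m >= 0.5), cc)
  }
  a <- maps@luad
  s <- maps@lusc
  rat <- function(x, y) (x + .ratioEps) / (y + .ratioEps)
  ratios <- c(
    rat(mean(a), mean(s)), rat(median(a), median(s)),
    rat(popVar(a), popVar(s)), rat(sum(a), sum(s)),
    vapply(.featThresholds,
           function(t) rat(sum(a >= t), sum(s >= t)), 0),
    vapply(.featThresholds,
           function(t) rat(.topComponents(a, t)[1], .topComponents(s, t)[1]),
           0))
  v <- c(perMap(a), perMap(s), ratios)
  stats::setNames(v, featureNames())
}

#' Select the most class-separating features
#'
#' Ranks features by the Fisher score
#' \code{(mu1 - mu2)^2 / (var1 + var2 + eps)} between the two slide classes
#' and returns the top \code{k}; ties resolve in canonical feature-name
#' order.
#'
#' @param features matrix or data.frame of slide feature vectors (rows =
#'   slides, columns = the 50 features).
#' @param labels slide labels ("LUAD"/"LUSC"), at least 2 slides per class.
#' @param k number of features to keep (default 25).
#' @return character vector of \code{k} selected feature names.
#' @export
selectFeatures <- function(features, labels, k = 25L) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) < 2L) stop("need slides from both classes")
  if (any(table(labels) < 2L)) stop("need at least 2 slides per class")
  i1 <- labels == cls[1]
  popVar <- function(x) mean((x - mean(x))^2)
  score <- vapply(seq_len(ncol(X)), function(j) {
    (mean(X[i1, j]) - mean(X[!i1, j]))^2 /
      (popVar(X[i1, j]) + popVar(X[!i1, j]) + 1e-12)
  }, 0)
  ord <- order(-score, seq_len(ncol(X)))
  colnames(X)[ord[seq_len(min(k, ncol(X)))]]
}

#' Classify a slide by max voting
#'
#' A patch is positive for the class holding its argmax; the slide takes the
#' class (LUAD vs LUSC) with more positive patches. Count ties fall back to
#' the larger summed probability mass, then to LUAD.
#'
#' @param maps a \code{\link{ProbabilityMaps}}.
#' @return \code{"LUAD"} or \code{"LUSC"}.
#' @export
maxVote <- function(maps) {
  if (length(maps@luad) == 0L) stop("empty probability maps")
  am <- argmaxMaps(maps)
  nLuad <- sum(am == 2L)
  nLusc <- sum(am == 3L)
  if (nLuad != nLusc) return(if (nLuad > nLusc) "LUAD" else "LUSC")
  mLuad <- sum(maps@luad)
  mLusc <- sum(maps@lusc)
  if (mLusc > mLuad) "LUSC" else "LUAD"
}

#' Train the random-forest regression slide classifier
#'
#' An ensemble of 10 bagged regression trees on the selected features, with
#' one third of the variables drawn per split and minimum leaf size 5;
#' labels are encoded LUAD = 0 / LUSC = 1 and the prediction is the mean of
#' the tree outputs.
#'
#' @param features matrix/data.frame of slide feature vectors.
#' @param labels slide labels ("LUAD"/"LUSC").
#' @param selected feature names to use (e.g. from
#'   \code{\link{selectFeatures}}); default all columns.
#' @param seed RNG seed (bagging and split sampling).
#' @return list of class \code{"SlideForest"} with the fitted forest and the
#'   feature names.
#' @export
trainRF <- function(features, labels, selected = NULL, seed = 1L) {
  X <- as.matrix(features)
  if (!is.null(selected)) X <- X[, selected, drop = FALSE]
  y <- ifelse(as.character(labels) == "LUSC", 1, 0)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (nrow(X) < 6L) stop("need at least 6 slides (minimum leaf size 5)")
  # regression on the 0/1 encoding is intentional (the forest outputs a
  # continuous score that is thresholded); silence the advisory warning
  fit <- withSeed(seed, suppressWarnings(randomForest::randomForest(
    x = X, y = y, ntree = 10L, mtry = ceiling(ncol(X) / 3),
    nodesize = 5L, replace = TRUE)))
  structure(list(forest = fit, features = colnames(X), seed = seed),
            class = "SlideForest")
}

#' Classify a slide with the regression forest
#'
#' @param model a \code{"SlideForest"} from \code{\link{trainRF}}.
#' @param features named feature vector (or 1-row matrix) of the slide.
#' @param threshold binarization threshold; regression output at or above it
#'   gives LUSC, below LUAD.
#' @return \code{"LUAD"} or \code{"LUSC"}.
#' @export
rfClassify <- function(model, features, threshold = 0.5) {
  x <- if (is.null(dim(features))) t(as.matrix(features))
       else as.matrix(features)
  x <- x[, model$features, drop = FALSE]
  out <- as.numeric(predict(model$forest, x))
  ifelse(out >= threshold, "LUSC", "LUAD")
}

#' Patch predictions for a set of slides
#'
#' Runs the patch classifier over every patch record and returns the
#' per-patch class probabilities with grid coordinates, ready for
#' \code{\link{assembleProbabilityMaps}}.
#'
#' @param net a \code{\link{TrainedNetwork}} patch classifier.
#' @param patches list of patch records (\code{image}, \code{slide},
#'   \code{row}, \code{col}).
#' @return data.frame with columns slide, row, col, p_nd, p_luad, p_lusc.
#' @export
predictPatches <- function(net, patches) {
  rows <- lapply(patches, function(p) {
    pr <- predictPatch(net, p$image)
    data.frame(slide = p$slide, row = p$row, col = p$col,
               p_nd = pr[["ND"]], p_luad = pr[["LUAD"]],
               p_lusc = pr[["LUSC"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Slide-level classification from patch predictions
#'
#' Assembles per-slide probability maps and classifies each slide by max
#' voting or with a trained regression forest.
#'
#' @param predictions data.frame from \code{\link{predictPatches}} (columns
#'   slide, row, col, p_nd, p_luad, p_lusc).
#' @param mode \code{"maxvote"} or \code{"rf"}.
#' @param model a \code{"SlideForest"} (required for \code{mode = "rf"}).
#' @param threshold RF binarization threshold.
#' @return data.frame with columns \code{slide} and \code{label}.
#' @export
classifySlides <- function(predictions, mode = c("maxvote", "rf"),
                           model = NULL, threshold = 0.5) {
  mode <- match.arg(mode)
  slides <- unique(predictions$slide)
  labs <- vapply(slides, function(s) {
    maps <- assembleProbabilityMaps(
      predictions[predictions$slide == s, , drop = FALSE])
    if (mode == "maxvote") maxVote(maps)
    else {
      if (is.null(model)) stop("mode 'rf' requires a trained model")
      rfClassify(model, extractFeatures(maps), threshold)
    }
  }, "")
  data.frame(slide = slides, label = unname(labs), stringsAsFactors = FALSE)
}
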