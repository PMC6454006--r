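#' @include AllGenerics.R
NULL

#' Read a labeled instance mask from TIFF
#'
#' Single-channel integer TIFF (16-bit, or 32-bit for ids above 65535). Ids
#' are preserved exactly and never relabeled.
#'
#' @param path TIFF file path.
#' @return integer matrix of instance ids.
#' @export
readLabeledMask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) != 2L)
    stop("labeled masks must be single-channel: ", path)
  if (!is.integer(x)) {
    if (max(abs(x - round(x))) > 0)
      stop("labeled masks must hold integer pixel values: ", path)
    storage.mode(x) <- "integer"
  }
  x
}

#' Write a labeled instance mask to TIFF
#'
#' 16-bit samples by default; switches to 32-bit when any id exceeds 65535 so
#' whole-slide-scale label counts cannot silently overflow.
#'
#' @param mask integer matrix of instance ids (>= 0).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeLabeledMask <- function(mask, path) {
  m <- as.matrix(mask)
  if (any(m < 0L)) stop("negative ids are not allowed")
  bits <- if (max(m, 0L) > 65535L) 32L else 16L
  tiff::writeTIFF(m / (2^bits - 1), path, bits.per.sample = bits)
  invisible(path)
}

#' Read / write an RGB tile image (PNG)
#'
#' @param path PNG file path.
#' @return numeric array (H, W, 3) in \code{[0, 1]}.
#' @export
readTileImage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), c(dim(x), 3L))
  x[, , 1:3, drop = FALSE]
}

#' @rdname readTileImage
#' @param image numeric array (H, W, 3) in \code{[0, 1]}.
#' @export
writeTileImage <- function(image, path) {
  png::writePNG(clamp01(image), path)
  invisible(path)
}

#' Write / read a tile with mask and metadata
#'
#' Stores \code{<id>.png} (image), \code{<id>_mask.tif} (labeled mask, if
#' present) and \code{<id>.json} (mpp, magnification) in a directory.
#'
#' @param tile a \code{\link{NucleiTile}}.
#' @param dir directory (created if needed).
#' @return the tile id, invisibly.
#' @export
writeTile <- function(tile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- tileId(tile)
  writeTileImage(tileImage(tile), file.path(dir, paste0(id, ".png")))
  if (!is.null(tileMask(tile)))
    writeLabeledMask(tileMask(tile), file.path(dir, paste0(id, "_mask.tif")))
  jsonlite::write_json(
    list(id = id, mpp = tileMpp(tile), magnification = tile@magnification),
    file.path(dir, paste0(id, ".json")), auto_unbox = TRUE, digits = NA)
  invisible(id)
}

#' @rdname writeTile
#' @param id tile id to read back.
#' @export
readTile <- function(dir, id) {
  meta <- jsonlite::read_json(file.path(dir, paste0(id, ".json")),
                              simplifyVector = TRUE)
  maskPath <- file.path(dir, paste0(id, "_mask.tif"))
  NucleiTile(readTileImage(file.path(dir, paste0(id, ".png"))),
             mask = if (file.exists(maskPath)) readLabeledMask(maskPath),
             mpp = meta$mpp, magnification = meta$magnification, id = meta$id)
}

#' Write / read slide feature tables
#'
#' CSV with a \code{slide} column, optionally a \code{label} column, and the
#' 50 feature columns in canonical order; values round-trip within 1e-9.
#' Non-finite feature values are refused.
#'
#' @param features data.frame with \code{slide}, optional \code{label}, and
#'   feature columns.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeFeaturesCSV <- function(features, path) {
  if (!"slide" %in% names(features)) stop("features need a 'slide' column")
  num <- setdiff(names(features), c("slide", "label"))
  vals <- as.matrix(features[, num, drop = FALSE])
  if (nrow(vals) && any(!is.finite(vals)))
    stop("non-finite feature values are not allowed")
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeaturesCSV
#' @export
readFeaturesCSV <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a patch manifest (JSON)
#'
#' One record per patch: slide id, 0-based grid row/col, image path, and
#' optionally the class label.
#'
#' @param manifest data.frame with columns \code{slide}, \code{row},
#'   \code{col}, \code{path} and optionally \code{label}.
#' @param path JSON file path.
#' @return the path, invisibly.
#' @export
writePatchManifest <- function(manifest, path) {
  need <- c("slide", "row", "col", "path")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns ", paste(need, collapse = ", "))
  jsonlite::write_json(manifest, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname writePatchManifest
#' @export
readPatchManifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# ---------------------------------------------------------------------------
# Run configuration
# ---------------------------------------------------------------------------

#' Default run configuration
#'
#' All tunable module parameters with their defaults: crop geometry, dataset
#' extraction counts, augmentation ranges, loss weights, optimizer settings,
#' inference thresholds, the physical area filter, and the slide-classifier
#' settings. Unknown keys are rejected when reading a config file, and
#' configs round-trip losslessly through JSON/YAML.
#'
#' @return named list of class \code{"RunConfig"}.
#' @export
defaultRunConfig <- function() {
  structure(list(
    seed = 1L,
    mpp_default_40x = 0.25, mpp_default_20x = 0.5,
    patch_side = 200L, input_side = 102L, output_side = 54L,
    nbl_step = 54L, nbl_random_crops = 30L,
    sn_center_side = 54L, sn_max_fraction = 0.5, sn_copies = 3L,
    border_thickness = 2L,
    aug_shift = c(-0.05, 0.05), aug_rotation = c(-45, 45),
    aug_flip_prob = 0.5, aug_shear = c(-0.4 * pi, 0.4 * pi),
    aug_resize = c(0.6, 2.0), aug_repeats = 3L,
    batch_size = 32L, l2_factor = 1e-5,
    loss_weights = c(5, 6, 1, 4),
    blob_threshold = 0.5, border_threshold = 0.5,
    min_area_um2 = 13,
    cls_patch_side = 256L, cls_crop_side = 224L,
    rf_trees = 10L, rf_min_leaf = 5L, rf_threshold = 0.5,
    feature_count = 50L, selected_features = 25L,
    device = "cpu"
  ), class = "RunConfig")
}

#' Read / write a run configuration (JSON or YAML by extension)
#'
#' @param path file path ending in .json, .yml or .yaml.
#' @return a \code{"RunConfig"} list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = , yaml = yaml::read_yaml(path),
    stop("unsupported config format: .", ext))
  def <- defaultRunConfig()
  unknown <- setdiff(names(vals), names(def))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  out <- modifyList(unclass(def), vals)
  # restore numeric storage modes lost by YAML/JSON round-trips
  for (k in names(out)) {
    if (is.integer(def[[k]])) out[[k]] <- as.integer(out[[k]])
    else if (is.double(def[[k]])) out[[k]] <- as.numeric(out[[k]])
  }
  structure(out, class = "RunConfig")
}

#' @rdname readRunConfig
#' @param config a \code{"RunConfig"} list.
#' @export
writeRunConfig <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  vals <- unclass(config)
  switch(ext,
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE,
                                digits = I(17)),
    yml = , yaml = yaml::write_yaml(vals, path, precision = 15L),
    stop("unsupported config format: .", ext))
  invisible(path)
}

#' Save / load a trained network checkpoint
#'
#' Serializes the \code{\link{TrainedNetwork}} (architecture, weights,
#' config, history) to an RDS archive.
#'
#' @param net a \code{\link{TrainedNetwork}}.
#' @param path checkpoint path (.rds).
#' @return the path (save) or the network (load).
#' @export
saveNetwork <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname saveNetwork
#' @export
loadNetwork <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  net <- readRDS(path)
  if (!is(net, "TrainedNetwork")) stop("not a network checkpoint: ", path)
  net
}
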