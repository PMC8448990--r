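# NIfTI volume I/O and YAML configuration.
#
# On disk, volumes follow the NIfTI (X, Y, Z) axis order; in memory the
# package stores (D, H, W) = (Z, Y, X), so readers and writers permute axes
# at the boundary. Case files pair `<case>_img.nii.gz` with
# `<case>_lbl.nii.gz`.

#' Read a volume from NIfTI
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @param labels validate and binarize the grid as a label volume (values must
#'   already be 0/1; anything else is an error listing the offending values).
#' @return List with `grid` (3D array in (D, H, W) order) and `spacing`
#'   (mm per (D, H, W) axis, from the header).
#' @export
readVolume <- function(path, labels = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop(sprintf("%s: expected a 3D volume, got %dD", path, length(dim(arr))))
  grid <- aperm(arr, c(3L, 2L, 1L))
  spacing <- rev(RNifti::pixdim(img)[1:3])
  if (labels) {
    bad <- setdiff(unique(as.vector(grid)), c(0, 1))
    if (length(bad))
      stop(sprintf("%s: label volume contains non-binary values: %s", path,
                   paste(utils::head(bad, 5), collapse = ", ")))
  }
  list(grid = grid, spacing = as.numeric(spacing))
}

#' Write a volume to NIfTI
#'
#' @param grid 3D array in (D, H, W) order.
#' @param path output path (`.nii.gz`).
#' @param spacing voxel size in mm per (D, H, W) axis, recorded in the header.
#' @param datatype NIfTI storage type; `"double"` round-trips intensities
#'   bit-exactly, `"uint8"` is compact for masks.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(grid, path, spacing = c(1, 1, 1), datatype = "double") {
  arr <- aperm(grid, c(3L, 2L, 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(as.numeric(spacing))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a labeled case from an image/label NIfTI pair
#'
#' @param imgPath,lblPath paths to the intensity and label volumes.
#' @return A [LabeledVolume-class].
#' @export
readCase <- function(imgPath, lblPath) {
  img <- readVolume(imgPath)
  lbl <- readVolume(lblPath, labels = TRUE)
  if (!identical(dim(img$grid), dim(lbl$grid)))
    stop(sprintf("shape mismatch between %s (%s) and %s (%s)", imgPath,
                 paste(dim(img$grid), collapse = "x"), lblPath,
                 paste(dim(lbl$grid), collapse = "x")))
  if (max(abs(img$spacing - lbl$spacing)) > 1e-4)
    stop(sprintf("spacing mismatch between %s and %s", imgPath, lblPath))
  labeledVolume(img$grid, lbl$grid, img$spacing)
}

#' Discover image/label case pairs in a directory
#'
#' @param dir directory containing `<case>_img.nii.gz` (and optionally
#'   `<case>_lbl.nii.gz`) files.
#' @return data.frame with columns case, img, lbl (NA when no label file).
#' @export
discoverCases <- function(dir) {
  imgs <- sort(list.files(dir, pattern = "_img\\.nii(\\.gz)?$", full.names = TRUE))
  if (length(imgs) == 0L) stop(sprintf("no *_img.nii[.gz] files in %s", dir))
  case <- sub("_img\\.nii(\\.gz)?$", "", basename(imgs))
  lbl <- file.path(dir, paste0(case, "_lbl.nii.gz"))
  lbl2 <- file.path(dir, paste0(case, "_lbl.nii"))
  lbl[!file.exists(lbl) & file.exists(lbl2)] <- lbl2[!file.exists(lbl) & file.exists(lbl2)]
  lbl[!file.exists(lbl)] <- NA_character_
  data.frame(case = case, img = imgs, lbl = lbl, stringsAsFactors = FALSE)
}

## ---- YAML configuration ----------------------------------------------------

#' Read pipeline configuration from YAML
#'
#' The file may contain `phantom`, `network`, `training` and `sliding`
#' sections whose keys match the corresponding constructor arguments
#' ([phantomSpec()], [networkConfig()], [trainingConfig()], [slidingSpec()]);
#' missing sections get the defaults.
#'
#' @param path YAML file path.
#' @return List with elements `phantom`, `network`, `training`, `sliding`.
#' @export
readConfigYaml <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(ctor, args) {
    if (is.null(args)) args <- list()
    lists <- vapply(args, is.list, logical(1))
    args[lists] <- lapply(args[lists], unlist)
    do.call(ctor, args)
  }
  list(phantom = build(phantomSpec, raw$phantom),
       network = build(networkConfig, raw$network),
       training = build(trainingConfig, raw$training),
       sliding = build(slidingSpec, raw$sliding))
}

## ---- run manifests ---------------------------------------------------------

s4_to_list <- function(x) {
  sn <- methods::slotNames(class(x))
  stats::setNames(lapply(sn, function(s) methods::slot(x, s)), sn)
}

write_manifest <- function(path, command, args, configs = list(),
                           inputs = character(0), outputs = character(0)) {
  checksums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    command = command,
    arguments = as.list(args),
    configs = lapply(configs, function(cf) if (isS4(cf)) s4_to_list(cf) else cf),
    input_checksums = checksums,
    outputs = as.list(outputs),
    package = "canalseg",
    version = as.character(utils::packageVersion("canalseg")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
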