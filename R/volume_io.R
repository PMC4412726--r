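#' Read a 3D volume from a NIfTI file
#'
#' Volumes are plain 3D numeric arrays in the file's native (i, j, k) axis
#' order with 1-based voxel indices; intensities are stored as doubles
#' regardless of the on-disk datatype. No world-space transform is applied:
#' the pipeline assumes spatially normalized grids, so voxel indices are the
#' working coordinate system.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A 3D numeric array with attribute `voxel_size_mm` (metadata only).
#' @export
read_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop(sprintf("cannot read volume: '%s' does not exist", path), call. = FALSE)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop(sprintf(
                    "cannot read volume '%s': not a readable NIfTI file (%s)",
                    path, conditionMessage(e)), call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L) dim(arr) <- dim(arr)[1:3]
  if (length(dim(arr)) != 3L)
    stop(sprintf("'%s' is not a 3D volume (dims: %s)", path,
                 paste(dim(arr), collapse = "x")), call. = FALSE)
  out <- array(as.double(arr), dim = dim(arr))
  attr(out, "voxel_size_mm") <- tryCatch(RNifti::pixdim(img)[1:3],
                                         error = function(e) c(1, 1, 1))
  out
}

#' Write a 3D volume to a NIfTI file
#'
#' @param v 3D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stop_if_not_volume(v)
  RNifti::writeNifti(RNifti::asNifti(array(as.double(v), dim = dim(v))), path)
  invisible(path)
}

#' Construct a brain atlas from a label volume and a name table
#'
#' @param labels 3D array of non-negative integer region codes; 0 marks
#'   background / non-brain voxels.
#' @param names Named character vector mapping region code (as name) to
#'   region name, e.g. `c("1" = "Precuneus_L")`. Every nonzero code present
#'   in `labels` must appear.
#' @return An object of class `brain_atlas`.
#' @export
brain_atlas <- function(labels, names) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("atlas labels must be a 3D array", call. = FALSE)
  lab <- array(as.integer(round(labels)), dim = dim(labels))
  if (any(lab < 0L)) stop("atlas labels must be non-negative", call. = FALSE)
  codes <- sort(unique(lab[lab > 0L]))
  if (is.null(base::names(names)))
    stop("'names' must be a named character vector (code -> region name)",
         call. = FALSE)
  nm <- stats::setNames(as.character(names), base::names(names))
  missing <- setdiff(as.character(codes), base::names(nm))
  if (length(missing))
    stop(sprintf("atlas labels contain codes without names: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  structure(list(labels = lab, names = nm), class = "brain_atlas")
}

#' @export
print.brain_atlas <- function(x, ...) {
  codes <- sort(unique(x$labels[x$labels > 0L]))
  cat(sprintf("Brain atlas: %s voxels, %d regions (%d in-brain voxels)\n",
              paste(dim(x$labels), collapse = "x"), length(codes),
              sum(x$labels > 0L)))
  invisible(x)
}

#' Read an atlas from a NIfTI label volume plus a code/name TSV
#'
#' The name table has two tab-separated columns: region code and region name,
#' no header.
#'
#' @param label_path NIfTI file with integer region codes.
#' @param names_path Two-column TSV (`code<TAB>name`).
#' @return A [brain_atlas] object.
#' @export
read_atlas <- function(label_path, names_path) {
  lab <- read_volume(label_path)
  tab <- utils::read.table(names_path, sep = "\t", header = FALSE,
                           colClasses = c("integer", "character"),
                           col.names = c("code", "name"))
  brain_atlas(lab, stats::setNames(tab$name, tab$code))
}

#' Build a brain mask from atlas regions
#'
#' @param atlas A [brain_atlas].
#' @param codes Integer vector of region codes, or `"all"` for every nonzero
#'   region (the default: all atlas-defined voxels).
#' @return Logical 3D array, `TRUE` at member voxels.
#' @export
mask_from_atlas <- function(atlas, codes = "all") {
  stopifnot(inherits(atlas, "brain_atlas"))
  m <- if (identical(codes, "all") || identical(codes, "all nonzero")) {
    atlas$labels > 0L
  } else {
    array(atlas$labels %in% as.integer(codes) & atlas$labels > 0L,
          dim = dim(atlas$labels))
  }
  if (!any(m)) stop("empty mask", call. = FALSE)
  m
}

#' Voxel coordinates of a mask
#'
#' @param mask Logical 3D array.
#' @return Integer matrix with one row per member voxel, columns x, y, z
#'   (1-based indices).
#' @export
voxel_coords <- function(mask) {
  out <- which(mask, arr.ind = TRUE)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Grand-mean intensity normalization
#'
#' Divides every voxel by the mean intensity over the brain mask, so the
#' masked mean becomes 1. Non-brain voxels are divided by the same constant
#' (they are excluded from the mean, not from the division, and are never
#' used downstream).
#'
#' @param v 3D numeric array.
#' @param mask Logical 3D array of brain voxels.
#' @return Normalized volume.
#' @export
grand_mean_normalize <- function(v, mask) {
  stop_if_not_volume(v)
  if (!identical(dim(v), dim(mask))) stop("mask shape mismatch", call. = FALSE)
  m <- mean(v[mask])
  if (!is.finite(m) || m <= 0)
    stop(sprintf("cannot normalize: masked mean is %s", format(m)), call. = FALSE)
  v / m
}

#' Reference-region (primary sensorimotor cortex) normalization
#'
#' Divides every voxel by the mean intensity over the union of the named
#' atlas regions. The default reference is the primary sensorimotor cortex:
#' left/right precentral and postcentral gyri.
#'
#' @param v 3D numeric array.
#' @param atlas A [brain_atlas].
#' @param region_names Character vector of region names forming the
#'   reference.
#' @return Normalized volume.
#' @export
psmc_normalize <- function(v, atlas,
                           region_names = c("Precentral_L", "Precentral_R",
                                            "Postcentral_L", "Postcentral_R")) {
  stop_if_not_volume(v)
  stopifnot(inherits(atlas, "brain_atlas"))
  if (!identical(dim(v), dim(atlas$labels)))
    stop("atlas shape mismatch", call. = FALSE)
  unknown <- setdiff(region_names, atlas$names)
  if (length(unknown))
    stop(sprintf("unknown atlas region name(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  codes <- as.integer(base::names(atlas$names)[atlas$names %in% region_names])
  ref <- atlas$labels %in% codes
  if (!any(ref)) stop("empty reference region", call. = FALSE)
  m <- mean(v[ref])
  if (!is.finite(m) || m <= 0)
    stop(sprintf("cannot normalize: reference mean is %s", format(m)), call. = FALSE)
  v / m
}

#' Voxel-wise mean of a set of volumes
#'
#' Used to form the mean normal-control reference image that the cluster
#' discovery runs on.
#'
#' @param volumes List of 3D numeric arrays of identical shape.
#' @return The voxel-wise arithmetic mean volume.
#' @export
mean_reference_image <- function(volumes) {
  if (!is.list(volumes) || length(volumes) < 1L)
    stop("need at least one volume", call. = FALSE)
  d <- dim(volumes[[1L]])
  for (v in volumes) {
    stop_if_not_volume(v)
    if (!identical(dim(v), d)) stop("volume shape mismatch", call. = FALSE)
  }
  Reduce(`+`, volumes) / length(volumes)
}
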