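## NIfTI label-volume container and I/O.
##
## Internal convention: voxels are stored as an integer 3D array indexed
## (z, y, x) with 1-based indices; spacing is the physical voxel size in mm
## per axis, ordered (z, y, x). NIfTI-1 files store data (x, y, z), so the
## reader/writer permute axes. Label codes: 0 background, 1 true lumen (TL),
## 2 false lumen (FL), 3 intimal flap (present only after flap extraction).

#' Construct a label volume
#'
#' @param voxels integer 3D array indexed (z, y, x) with values in
#'   \{0, 1, 2, 3\}: background, true lumen, false lumen, intimal flap.
#' @param spacing numeric length-3 vector of voxel sizes in mm, (z, y, x).
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing) {
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)[c(3, 1, 2)]
  storage.mode(voxels) <- "integer"
  spacing <- as.numeric(spacing)
  names(spacing) <- c("z", "y", "x")
  vol <- structure(list(voxels = voxels, spacing = spacing),
                   class = "label_volume")
  validate_label_volume(vol)
  vol
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_volume> %d x %d x %d voxels (z, y, x), spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  tab <- table(factor(x$voxels, levels = LABEL_SET,
                      labels = c("background", "TL", "FL", "flap")))
  print(tab)
  invisible(x)
}

#' Validate a label volume against its invariants
#'
#' Checks that the grid is a 3D integer array with all values in
#' \{0, 1, 2, 3\}, and that all spacing components are strictly positive
#' and finite.
#'
#' @param vol a `label_volume`.
#' @return `vol`, invisibly, if valid; otherwise a validation error.
#' @export
validate_label_volume <- function(vol) {
  if (!inherits(vol, "label_volume"))
    stop_validation("not a label_volume object")
  d <- dim(vol$voxels)
  if (length(d) != 3L || any(d < 1L))
    stop_validation("voxel grid must be 3D with all dimensions >= 1 (got %s)",
                    paste(d, collapse = " x "))
  if (length(vol$spacing) != 3L || any(!is.finite(vol$spacing)) ||
      any(vol$spacing <= 0))
    stop_validation("spacing must be three strictly positive finite values (got %s)",
                    paste(signif(vol$spacing, 6), collapse = ", "))
  bad <- setdiff(unique(as.vector(vol$voxels)), LABEL_SET)
  if (length(bad) > 0L)
    stop_validation("labels outside {0,1,2,3} present: %s",
                    paste(sort(bad), collapse = ", "))
  invisible(vol)
}

#' Read a multi-label segmentation volume from NIfTI-1
#'
#' Reads a 3D integer-valued NIfTI file, normalises the axis order to
#' (z, y, x), takes the voxel spacing from the file header, and enforces
#' the package label convention (values in \{0, 1, 2, 3\}). Values stored
#' as floats are accepted when within 1e-6 of an integer. A label-remap
#' table can translate foreign label schemes at read time.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param remap optional remap table: a data frame with columns
#'   `source_label` and `target_label`, or the path of a CSV file with
#'   those columns. Unlisted labels pass through unchanged.
#' @return a [label_volume()].
#' @export
read_label_volume <- function(path, remap = NULL) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) > 3L) {
    if (all(d[-(1:3)] == 1L)) {
      dim(arr) <- d[1:3]
    } else {
      stop_format("expected a 3D image, got %dD with dimensions %s",
                  length(d), paste(d, collapse = " x "))
    }
  }
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (is.double(arr)) {
    if (max(abs(arr - round(arr))) > 1e-6)
      stop_format("voxel values are not integer-representable (max deviation %.3g)",
                  max(abs(arr - round(arr))))
    arr <- round(arr)
  }
  storage.mode(arr) <- "integer"
  if (!is.null(remap)) {
    if (is.character(remap)) remap <- read.csv(remap)
    if (!all(c("source_label", "target_label") %in% names(remap)))
      stop_validation("remap table needs columns source_label, target_label")
    m <- match(arr, as.integer(remap$source_label))
    arr[!is.na(m)] <- as.integer(remap$target_label)[m[!is.na(m)]]
  }
  pd <- RNifti::pixdim(img)
  spacing_xyz <- rep_len(as.numeric(pd), 3L)
  vol <- label_volume(aperm(arr, c(3, 2, 1)), rev(spacing_xyz))
  vol
}

#' Write a label volume to NIfTI-1
#'
#' Writes a file that [read_label_volume()] reproduces exactly on voxels,
#' and on spacing to the precision representable in the NIfTI header. The
#' volume is validated before any file is created.
#'
#' @param volume a [label_volume()].
#' @param path destination path (`.nii` or `.nii.gz`); the parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  validate_label_volume(volume)
  if (!dir.exists(dirname(path)))
    stop_io("parent directory does not exist: %s", dirname(path))
  arr <- aperm(volume$voxels, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(volume$spacing)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Extract one axial slice from a label volume
#'
#' @param volume a [label_volume()].
#' @param z 1-based slice index, `1 <= z <= dim(volume$voxels)[1]`.
#' @return a `label_slice`: list with `grid` (2D integer matrix indexed
#'   (y, x)) and `spacing` (in-plane (y, x) voxel size in mm).
#' @export
extract_slice <- function(volume, z) {
  validate_label_volume(volume)
  nz <- dim(volume$voxels)[1]
  if (length(z) != 1L || !is.finite(z) || z != round(z) || z < 1L || z > nz)
    stop_index("slice index %s out of range [1, %d]", as.character(z), nz)
  structure(list(grid = volume$voxels[z, , ],
                 spacing = unname(volume$spacing[c("y", "x")])),
            class = "label_slice")
}

## In-plane (y, x) spacing of a volume.
spacing_yx <- function(volume) unname(volume$spacing[c(2, 3)])
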