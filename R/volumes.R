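#' Scalar volume on a regular grid
#'
#' The basic container shared by all modules: a 3D scalar array with physical
#' voxel spacing and origin. Voxel indices are 0-based in all physical-space
#' arithmetic; the physical position of voxel (i, j, k) is
#' `origin + c(i, j, k) * spacing`. Only axis-aligned geometry (identity
#' direction cosines) is supported.
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, voxel size in mm (strictly positive).
#' @param origin Numeric length-3, physical position of voxel (0,0,0) in mm.
#' @param kind Intensity kind: one of `"HU"`, `"normalized"`,
#'   `"log2_jacobian"`, `"jacobian"`, `"label"`.
#' @return A `jr_volume` object.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     kind = c("HU", "normalized", "log2_jacobian",
                              "jacobian", "label")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L) stop("expected 3D volume")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must have length 3")
  structure(list(data = data, spacing = spacing, origin = origin, kind = kind),
            class = "jr_volume")
}

#' @export
print.jr_volume <- function(x, ...) {
  cat(sprintf("<jr_volume %s> %s, spacing %s mm\n", x$kind,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Binary lung mask
#'
#' @param data 3D array of 0/1 values.
#' @inheritParams volume3d
#' @return A `jr_mask` object (also a `jr_volume` with kind `"label"`).
#' @export
lung_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1))) stop("mask values must be 0 or 1")
  if (!any(data == 1)) stop("mask must contain at least one voxel")
  v <- volume3d(data, spacing, origin, kind = "label")
  class(v) <- c("jr_mask", class(v))
  v
}

#' ROI label map
#'
#' Integer labels partitioning a lung mask; 0 means outside the lung.
#'
#' @param data 3D integer array of labels.
#' @param label_table Named integer vector or list mapping label value to name.
#' @inheritParams volume3d
#' @return A `jr_labelmap` object.
#' @export
roi_label_map <- function(data, label_table, spacing = c(1, 1, 1),
                          origin = c(0, 0, 0)) {
  v <- volume3d(data, spacing, origin, kind = "label")
  v$label_table <- label_table
  class(v) <- c("jr_labelmap", class(v))
  v
}

#' Check that a label map partitions a mask
#'
#' Every in-mask voxel must carry exactly one nonzero label and every nonzero
#' label must lie inside the mask.
#' @param rois A `jr_labelmap`.
#' @param mask A `jr_mask` on the same grid.
#' @return TRUE invisibly, or an error.
#' @export
check_partition <- function(rois, mask) {
  same_grid(rois, mask)
  inmask <- mask$data == 1
  if (any(rois$data[inmask] == 0))
    stop("labels do not cover the mask (unlabelled in-mask voxels)")
  if (any(rois$data[!inmask] != 0))
    stop("nonzero labels found outside the mask")
  invisible(TRUE)
}

same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grid shape mismatch")
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("voxel spacing mismatch")
  invisible(TRUE)
}

#' Read a volume from a NIfTI file
#'
#' Accepts only 3D, axis-aligned (identity direction cosine) images; oblique
#' orientations and 4D images are rejected.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param kind Intensity kind to tag the result with (not stored in NIfTI).
#' @return A `jr_volume`.
#' @export
read_volume <- function(path, kind = "HU") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected 3D volume, got ", length(d), "D")
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  sp <- sqrt(colSums(rot^2))
  dircos <- sweep(abs(rot), 2, sp, "/")
  if (max(abs(dircos - diag(3))) > 1e-4)
    stop("non-axis-aligned (oblique) orientation is not supported")
  volume3d(array(as.numeric(img), dim = d), spacing = sp,
           origin = as.numeric(xf[1:3, 4]), kind = kind)
}

#' Write a volume to a NIfTI file
#'
#' Label/mask volumes are stored with an integer datatype, all others as
#' 32-bit float. Any non-finite voxel is an error.
#'
#' @param v A `jr_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "jr_volume"))
  if (any(!is.finite(v$data))) stop("volume contains non-finite values")
  dt <- if (v$kind == "label") "int32" else "float"
  arr <- v$data
  attr(arr, "pixdim") <- v$spacing
  img <- RNifti::asNifti(arr, datatype = dt)
  aff <- structure(rbind(cbind(diag(v$spacing), v$origin), c(0, 0, 0, 1)),
                   code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read / write a displacement field as 4D NIfTI
#'
#' The fourth axis holds the three vector components, in mm.
#' @param path File path.
#' @return For `read_displacement_field`, a list with `u` (4D array,
#'   last dim 3), `spacing`, `origin`.
#' @export
read_displacement_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4D displacement field with 3 components")
  sp <- RNifti::pixdim(img)[1:3]
  list(u = array(as.numeric(img), dim = d), spacing = sp, origin = c(0, 0, 0))
}

#' @rdname read_displacement_field
#' @param u 4D array (D, H, W, 3) of displacements in mm.
#' @param spacing Voxel spacing in mm.
#' @export
write_displacement_field <- function(u, spacing, path) {
  if (length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("expected a 4D displacement field with 3 components")
  if (any(!is.finite(u))) stop("field contains non-finite values")
  attr(u, "pixdim") <- c(spacing, 1)
  img <- RNifti::asNifti(u, datatype = "float")
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Union bounding box of two masks
#'
#' Tightest axis-aligned box containing every set voxel of either mask,
#' returned as 0-based half-open index intervals: `lo` (inclusive) and
#' `hi` (exclusive) per axis.
#'
#' @param a,b `jr_mask` objects on the same grid.
#' @return List with integer vectors `lo`, `hi` (length 3).
#' @export
bounding_box_union <- function(a, b) {
  same_grid(a, b)
  u <- (a$data == 1) | (b$data == 1)
  if (!any(u)) stop("empty union")
  idx <- which(u, arr.ind = TRUE)
  list(lo = as.integer(apply(idx, 2, min) - 1L),
       hi = as.integer(apply(idx, 2, max)))
}

# R slice indices (1-based, inclusive) for a half-open box
box_slices <- function(box) {
  lapply(1:3, function(ax) seq.int(box$lo[ax] + 1L, box$hi[ax]))
}

crop_to_box <- function(v, box) {
  s <- box_slices(box)
  out <- v
  out$data <- v$data[s[[1]], s[[2]], s[[3]], drop = FALSE]
  out$origin <- v$origin + box$lo * v$spacing
  out
}
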