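#' Construct a label volume
#'
#' A `label_volume` is the geometric unit every measurement in this package
#' runs on: a 3D integer array of labels (0 = background, k > 0 = label k)
#' together with the physical voxel spacing in mm along each array axis and
#' the index of the through-plane (axial stacking) axis. Abdominal DWI stacks
#' are strongly anisotropic (roughly 1-2 mm in plane, 4-5 mm between slices),
#' so the slice axis matters for every in-plane measurement.
#'
#' The physical position of voxel `(i, j, k)` (1-based array indices) is
#' `(i-1, j-1, k-1) * spacing`; all distances in the package are between
#' voxel centers under this convention.
#'
#' @param voxels 3D array of non-negative integers (or floats within `1e-6`
#'   of integers).
#' @param spacing Numeric length-3 vector, mm per voxel along each array axis;
#'   all components must be positive.
#' @param slice_axis Axis index in `1:3` of the through-plane axis, or `NULL`
#'   to infer it as the largest-spacing axis.
#' @param origin,orientation Optional header metadata carried through I/O
#'   untouched; not used by any measurement.
#' @return An object of class `label_volume`.
#' @examples
#' vox <- array(0L, dim = c(8, 8, 4))
#' vox[3:5, 3:5, 2] <- 1L
#' vol <- label_volume(vox, spacing = c(1.5, 1.5, 5))
#' vol$slice_axis   # 3: inferred from the 5 mm spacing
#' @export
label_volume <- function(voxels, spacing, slice_axis = NULL,
                         origin = NULL, orientation = NULL) {
  if (length(dim(voxels)) != 3L)
    stop("unsupported dimensionality: 'voxels' must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite numbers (mm)")
  voxels <- coerce_integer_voxels(voxels)
  if (any(voxels < 0L))
    stop("not a label volume: negative voxel values")
  if (is.null(slice_axis)) slice_axis <- which.max(spacing)
  slice_axis <- as.integer(slice_axis)
  if (length(slice_axis) != 1L || is.na(slice_axis) || !slice_axis %in% 1:3)
    stop("'slice_axis' must be 1, 2 or 3")
  structure(
    list(voxels = voxels, spacing = spacing, slice_axis = slice_axis,
         origin = origin, orientation = orientation),
    class = "label_volume"
  )
}

# Round float storage to integers, refusing values that are not within
# tolerance of an integer (a probability map is not a label volume).
coerce_integer_voxels <- function(voxels, tol = 1e-6) {
  d <- dim(voxels)
  if (is.integer(voxels)) return(array(as.integer(voxels), dim = d))
  v <- as.numeric(voxels)
  r <- round(v)
  if (any(abs(v - r) > tol, na.rm = TRUE) || anyNA(v))
    stop("not a label volume: voxel values are not integers (tolerance 1e-6)")
  array(as.integer(r), dim = d)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("label_volume: %d x %d x %d voxels, spacing (%g, %g, %g) mm, slice axis %d\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$slice_axis))
  labs <- sort(unique(as.vector(x$voxels)))
  cat(sprintf("  labels: {%s}; foreground voxels: %d\n",
              paste(labs, collapse = ", "), sum(x$voxels > 0L)))
  invisible(x)
}

#' Read a 3D label mask from a NIfTI file
#'
#' Reads a `.nii` or `.nii.gz` file into a [label_volume]. Voxel spacing is
#' taken from the header `pixdim`; the slice axis defaults to the axis with
#' the largest spacing (axial stacks of anisotropic abdominal DWI), which can
#' be overridden for isotropic or unusually ordered data. A 4D image with a
#' trailing singleton dimension is accepted and squeezed.
#'
#' @param path Path to a readable NIfTI file containing integer-valued data
#'   (float storage is accepted when every value is within `1e-6` of an
#'   integer).
#' @param slice_axis_override Optional axis index in `1:3` forcing the
#'   through-plane axis.
#' @return A [label_volume].
#' @seealso [write_mask()], [check_geometry_match()]
#' @export
read_mask <- function(path, slice_axis_override = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img_arr <- array(as.vector(img), dim = d[1:3])
  } else if (length(d) == 3L) {
    img_arr <- array(as.vector(img), dim = d)
  } else {
    stop(sprintf("unsupported dimensionality: %dD image (need 3D or trailing-singleton 4D)",
                 length(d)))
  }
  spacing <- RNifti::pixdim(img)[1:3]
  label_volume(img_arr, spacing = spacing, slice_axis = slice_axis_override,
               origin = RNifti::origin(img),
               orientation = RNifti::xform(img))
}

#' Write a label volume to a NIfTI file
#'
#' Round-trip contract: `read_mask(write_mask(v, p))` reproduces the voxel
#' array exactly and the spacing within float32 header precision.
#'
#' @param vol A [label_volume].
#' @param path Output path (`.nii` or `.nii.gz`; gzip inferred from the
#'   extension).
#' @return `path`, invisibly.
#' @export
write_mask <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that two volumes live on the same grid
#'
#' Every comparison in the package (liver vs tumour mask, predicted vs
#' reference, baseline vs follow-up) assumes a shared voxel grid; this is the
#' predicate that enforces it. No resampling is ever attempted.
#'
#' @param a,b [label_volume] objects.
#' @param tol Relative tolerance on spacing agreement (default `1e-3`).
#' @return `TRUE` iff the array shapes are equal and spacings agree within
#'   `tol` relative.
#' @export
check_geometry_match <- function(a, b, tol = 1e-3) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  if (!identical(dim(a$voxels), dim(b$voxels))) return(FALSE)
  rel <- abs(a$spacing - b$spacing) / pmax(abs(a$spacing), abs(b$spacing))
  all(rel <= tol)
}

# Binarize a possibly multi-label mask; warn once when collapsing labels.
binarize_mask <- function(vol) {
  labs <- unique(as.vector(vol$voxels))
  if (any(labs > 1L))
    warning("multi-label mask binarized: all labels > 0 treated as foreground")
  vol$voxels <- array(as.integer(vol$voxels > 0L), dim = dim(vol$voxels))
  vol
}
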