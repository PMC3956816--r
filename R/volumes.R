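#' CT volume container
#'
#' A 3D grid of CT numbers (Hounsfield units) with physical voxel spacing.
#' Axis convention: the first array index runs left-right (x), the second
#' anterior-posterior (y), the third inferior-superior (z, axial slices
#' stacked bottom to top). Voxel centers sit at `(i-1)*dx` mm etc., so the
#' first voxel center is the coordinate origin.
#'
#' @param values 3D numeric array of CT numbers (HU).
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in mm; all
#'   strictly positive. The default acquisition geometry of the system this
#'   package models is 0.781 x 0.781 x 3.0 mm, but any positive spacing is
#'   accepted.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing = c(0.781, 0.781, 3.0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (any(dim(values) < 1L)) stop("ct_volume: grid must be non-empty")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("ct_volume: spacing must be 3 strictly positive numbers (mm)")
  structure(list(values = values, spacing = spacing, unit = "HU"),
            class = "ct_volume")
}

#' Calibrated density volume
#'
#' Same geometry as [ct_volume()] but voxel values are equivalent aqueous
#' K2HPO4 densities in mg/cm^3. Negative values are valid (fat-rich tissue).
#'
#' @param values 3D numeric array, mg/cm^3.
#' @param spacing voxel spacing in mm.
#' @param fit optional [calibration_fit] that produced the volume.
#' @return An object of class `calibrated_volume`.
#' @export
calibrated_volume <- function(values, spacing = c(0.781, 0.781, 3.0),
                              fit = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("calibrated_volume: spacing must be 3 strictly positive numbers (mm)")
  structure(list(values = values, spacing = spacing, unit = "mg/cm3",
                 fit = fit),
            class = "calibrated_volume")
}

#' Bone mask
#'
#' Logical grid aligned with a calibrated volume: TRUE marks voxels inside
#' the proximal-femur bone envelope.
#'
#' @param mask 3D logical array.
#' @param spacing voxel spacing in mm, inherited from the source volume.
#' @return An object of class `bone_mask`.
#' @export
bone_mask <- function(mask, spacing) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, is.logical(mask))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("bone_mask: spacing must be 3 strictly positive numbers (mm)")
  structure(list(mask = mask, spacing = spacing), class = "bone_mask")
}

#' @export
dim.ct_volume <- function(x) dim(x$values)
#' @export
dim.calibrated_volume <- function(x) dim(x$values)
#' @export
dim.bone_mask <- function(x) dim(x$mask)

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels @ %.3f x %.3f x %.3f mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$values), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.calibrated_volume <- function(x, ...) {
  cat(sprintf("<calibrated_volume> %s voxels @ %.3f x %.3f x %.3f mm, mg/cm3 range [%.1f, %.1f]\n",
              paste(dim(x$values), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.bone_mask <- function(x, ...) {
  cat(sprintf("<bone_mask> %s voxels @ %.3f x %.3f x %.3f mm, %d bone voxels\n",
              paste(dim(x$mask), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3], sum(x$mask)))
  invisible(x)
}

# voxel centre coordinates (mm) along one axis; 0-based centres
axis_coords <- function(n, h) (seq_len(n) - 1) * h

# voxel volume in cm^3 for spacing in mm
voxel_volume_cm3 <- function(spacing) prod(spacing) / 1000

#' Axis-aligned sub-volume box
#'
#' Voxel-index box used to restrict segmentation to a region of interest.
#' Indices are 1-based and inclusive (R convention); a helper accepting mm
#' coordinates converts via the voxel-centre convention.
#'
#' @param lo,hi integer length-3 vectors, inclusive corner indices.
#' @return An object of class `voxel_box`.
#' @export
voxel_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(length(lo) == 3, length(hi) == 3)
  if (any(hi < lo)) stop("voxel_box: hi must be >= lo on every axis")
  structure(list(lo = lo, hi = hi), class = "voxel_box")
}

#' @param lo_mm,hi_mm box corners in mm (voxel-centre coordinates).
#' @param spacing voxel spacing in mm.
#' @param dims grid dimensions, used to clamp the box.
#' @rdname voxel_box
#' @export
voxel_box_mm <- function(lo_mm, hi_mm, spacing, dims) {
  lo <- pmax(1L, as.integer(floor(lo_mm / spacing)) + 1L)
  hi <- pmin(as.integer(dims), as.integer(ceiling(hi_mm / spacing)) + 1L)
  voxel_box(lo, hi)
}

check_box <- function(box, dims) {
  if (is.null(box)) return(voxel_box(c(1L, 1L, 1L), dims))
  stopifnot(inherits(box, "voxel_box"))
  if (any(box$lo < 1L) || any(box$hi > dims))
    stop("geometry error: box extends outside the volume grid")
  box
}
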