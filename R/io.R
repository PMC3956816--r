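#' Read a CT volume from disk
#'
#' Reads a NIfTI file (`.nii`, `.nii.gz`, `.hdr`) into a [ct_volume()],
#' taking the voxel spacing from the header. Slice ordering follows the
#' file's third axis (inferior to superior). DICOM series directories and
#' NRRD files are not supported by this build and fail with a clear
#' message; convert them to NIfTI first (e.g. with dcm2niix).
#'
#' @param path file path.
#' @return A [ct_volume()].
#' @export
read_ct_volume <- function(path) {
  if (dir.exists(path))
    stop("format error: DICOM series directories are not supported; ",
         "convert the series to NIfTI (e.g. dcm2niix) and pass the .nii file")
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nrrd")
    stop("format error: NRRD is not supported; convert to NIfTI first")
  if (!ext %in% c("nii", "hdr", "img"))
    stop("format error: unrecognized volume format '", ext, "'")
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) == 4 && dim(vals)[4] == 1) dim(vals) <- dim(vals)[1:3]
  if (length(dim(vals)) != 3)
    stop("format error: expected a 3D volume, got ",
         length(dim(vals)), " dimensions")
  sp <- abs(RNifti::pixdim(img))[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("format error: missing or invalid pixel spacing in header")
  ct_volume(vals, spacing = sp)
}

#' Write a volume or mask as NIfTI
#'
#' @param x a [ct_volume()], [calibrated_volume()] or [bone_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume_nifti <- function(x, path) {
  vals <- if (inherits(x, "bone_mask")) x$mask * 1L else x$values
  sp <- x$spacing
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a projection image
#'
#' Writes the raw aBMD, mass and path-volume maps as CSV (one file per
#' map, pixels in x rows by z columns) or renders a windowed aBMD PNG.
#'
#' @param proj a `projection_image`.
#' @param prefix output path prefix for CSVs.
#' @export
write_projection_csv <- function(proj, prefix) {
  utils::write.csv(proj$abmd_gcm2, paste0(prefix, "_abmd_gcm2.csv"),
                   row.names = FALSE)
  utils::write.csv(proj$mass_g, paste0(prefix, "_mass_g.csv"),
                   row.names = FALSE)
  utils::write.csv(proj$volume_cm3, paste0(prefix, "_volume_cm3.csv"),
                   row.names = FALSE)
  invisible(prefix)
}

#' @param rois optional `hip_roi_set` whose region outlines are overlaid.
#' @param path PNG output path.
#' @rdname write_projection_csv
#' @export
write_projection_png <- function(proj, path, rois = NULL) {
  ab <- proj$abmd_gcm2
  mx <- max(ab)
  g <- if (mx > 0) ab / mx else ab
  # image convention: rows top-to-bottom = superior-to-inferior
  g <- t(g[, ncol(g):1, drop = FALSE])
  rgb <- array(g, c(dim(g), 3))
  if (!is.null(rois)) {
    lab <- t(rois$labels[, ncol(rois$labels):1, drop = FALSE])
    edge <- lab != rbind(lab[-1, , drop = FALSE], lab[nrow(lab), ]) |
      lab != cbind(lab[, -1, drop = FALSE], lab[, ncol(lab)])
    cols <- matrix(c(1, 0.2, 0.2, 0.2, 1, 0.2, 0.3, 0.5, 1), 3, byrow = TRUE)
    for (l in 1:3) {
      m <- edge & lab == l
      for (ch in 1:3) {
        plane <- rgb[, , ch]; plane[m] <- cols[l, ch]; rgb[, , ch] <- plane
      }
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
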