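#' Rigid rotation record
#'
#' Orthonormal rotation (determinant +1) with its centre and the estimated
#' pre-rotation shaft and neck axes.
#'
#' @param R 3x3 rotation matrix (maps pre-rotation directions to the
#'   standard pose: shaft to +z, in-plane neck component to +x).
#' @param center centre of rotation, mm.
#' @param shaft_axis,neck_axis unit vectors in the pre-rotation frame.
#' @export
rigid_rotation <- function(R, center, shaft_axis = NULL, neck_axis = NULL) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3, 3)))
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
    stop("rigid_rotation: matrix must be orthonormal with determinant +1")
  structure(list(R = R, center = as.numeric(center),
                 shaft_axis = shaft_axis, neck_axis = neck_axis),
            class = "rigid_rotation")
}

#' Rotation matrix about a coordinate axis
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @param angle_deg rotation angle in degrees (right-handed).
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  c0 <- cos(a); s0 <- sin(a)
  R <- diag(3)
  ij <- switch(axis, c(2, 3), c(3, 1), c(1, 2))
  R[ij[1], ij[1]] <- c0; R[ij[2], ij[2]] <- c0
  R[ij[1], ij[2]] <- -s0; R[ij[2], ij[1]] <- s0
  R
}

#' Angle of a rotation matrix in degrees
#' @param R 3x3 rotation matrix.
#' @export
rotation_angle_deg <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

normalize3 <- function(v) v / sqrt(sum(v^2))

#' Estimate the standard-pose rotation from a segmented femur
#'
#' The shaft axis is the first principal axis of the mask voxel positions
#' in the distal 40% (lowest z) of the mask. The head centre is located by
#' mean-shift around the voxel farthest from the shaft line, and the neck
#' axis is the first principal axis of the voxels in a corridor around the
#' chord from the shaft line to the head centre. The returned rotation
#' maps the shaft axis to +z and the component of the neck axis orthogonal
#' to z to +x, i.e. the shaft becomes vertical in the coronal and sagittal
#' views and the neck horizontal in the axial view.
#'
#' @param mask a [bone_mask()].
#' @param volume optional [calibrated_volume()] (unused by the geometric
#'   estimator, accepted for interface symmetry).
#' @param head_window_mm mean-shift window radius for the head centre.
#' @return A [rigid_rotation()].
#' @export
estimate_standard_rotation <- function(mask, volume = NULL,
                                       head_window_mm = 25) {
  stopifnot(inherits(mask, "bone_mask"))
  if (!any(mask$mask)) stop("orientation failure: empty mask")
  idx <- which(mask$mask, arr.ind = TRUE)
  if (length(unique(idx[, 3])) < 20)
    stop("orientation failure: mask spans fewer than 20 axial slices")
  p <- sweep(idx - 1, 2, mask$spacing, `*`)   # mm coordinates
  zr <- range(p[, 3])
  distal <- p[p[, 3] <= zr[1] + 0.4 * diff(zr), , drop = FALSE]
  ev <- eigen(stats::cov(distal), symmetric = TRUE)
  # isotropic blobs (spheres) have near-equal principal variances; a shaft
  # keeps a clear leading axis even when tilted by 20 degrees or more
  if (ev$values[1] < 1.3 * ev$values[2])
    stop("orientation failure: degenerate principal axes; supply manual angles")
  # shaft axis through the per-slice centroids of the distal region, with
  # outlier slices (lesser trochanter, oblique end cuts) rejected so
  # protrusions do not tilt the estimate
  sl <- split(seq_len(nrow(distal)), distal[, 3])
  cz <- as.numeric(names(sl))
  cx <- vapply(sl, function(i) mean(distal[i, 1]), numeric(1))
  cy <- vapply(sl, function(i) mean(distal[i, 2]), numeric(1))
  ns <- vapply(sl, length, numeric(1))
  # slices whose cross-sectional area jumps carry a protrusion (lesser
  # trochanter); the line itself is fitted by long-baseline Theil-Sen,
  # which shrugs off both remaining outlier slices and the staircase that
  # slice-quantized masks produce under rotation
  use <- ns <= 1.02 * stats::median(ns)
  if (sum(use) < 5) use <- rep(TRUE, length(cz))
  ts_fit <- function(v, w) {
    zz <- cz[w]; vv <- v[w]
    dz <- outer(zz, zz, `-`)
    pair <- which(dz >= 10, arr.ind = TRUE)
    if (nrow(pair) == 0) pair <- which(dz > 0, arr.ind = TRUE)
    sl <- stats::median((vv[pair[, 1]] - vv[pair[, 2]]) /
                          (zz[pair[, 1]] - zz[pair[, 2]]))
    c(slope = sl, intercept = stats::median(vv - sl * zz))
  }
  for (i in 1:2) {
    fx <- ts_fit(cx, use); fy <- ts_fit(cy, use)
    res <- sqrt((cx - fx[2] - fx[1] * cz)^2 + (cy - fy[2] - fy[1] * cz)^2)
    keep <- use & res <= pmax(1.0, 3 * stats::median(res[use]))
    if (sum(keep) < 5) break
    use <- keep
  }
  fx <- ts_fit(cx, use); fy <- ts_fit(cy, use)
  shaft <- normalize3(c(fx[1], fy[1], 1))
  zm <- mean(cz[use])
  ctr <- c(fx[2] + fx[1] * zm, fy[2] + fy[1] * zm, zm)
  if (shaft[3] < 0) shaft <- -shaft
  # head centre: mean-shift from the voxel farthest from the shaft line
  rel <- sweep(p, 2, ctr)
  t <- rel %*% shaft
  perp2 <- rowSums(rel^2) - t^2
  H <- p[which.max(perp2), ]
  for (i in 1:3) {
    near <- rowSums(sweep(p, 2, H)^2) <= head_window_mm^2
    H <- colMeans(p[near, , drop = FALSE])
  }
  S <- ctr + sum((H - ctr) * shaft) * shaft   # shaft point nearest head
  chord <- H - S
  L <- sqrt(sum(chord^2))
  if (L < 1e-6) stop("orientation failure: head centre on shaft axis")
  u0 <- chord / L
  relS <- sweep(p, 2, S)
  tt <- relS %*% u0
  pp2 <- rowSums(relS^2) - tt^2
  band <- tt >= 0.25 * L & tt <= 0.8 * L & pp2 <= 16^2
  neck <- u0
  if (sum(band) >= 50) {
    evn <- eigen(stats::cov(p[band, , drop = FALSE]), symmetric = TRUE)
    cand <- evn$vectors[, 1]
    if (sum(cand * u0) < 0) cand <- -cand
    if (sum(cand * u0) > cos(45 * pi / 180)) neck <- cand
  }
  w <- normalize3(shaft)
  # azimuth from the shaft-to-head chord: it equals the in-plane neck
  # component for an in-plane neck and is insensitive to band asymmetry
  nperp <- chord - sum(chord * w) * w
  if (sqrt(sum(nperp^2)) < 1e-6)
    stop("orientation failure: neck axis parallel to shaft axis")
  u <- normalize3(nperp)
  R <- rbind(u, cross3(w, u), w)
  dimnames(R) <- NULL
  rigid_rotation(R, center = colMeans(p), shaft_axis = w, neck_axis = neck)
}

#' Resample a masked volume into the standard pose
#'
#' Rotates the calibrated density restricted to the bone mask onto an
#' isotropic grid by trilinear interpolation. Mask occupancy is
#' interpolated alongside and thresholded at 0.5; interpolated density in
#' retained voxels is occupancy-normalized so boundary voxels keep
#' physical density values and total mass is conserved to about 1%.
#' Voxels outside the bone carry `NA` (zero is a valid density).
#'
#' @param volume a [calibrated_volume()].
#' @param mask a [bone_mask()] on the same grid.
#' @param rot a [rigid_rotation()]; identity (with the mask centroid as
#'   centre) if `NULL`.
#' @param iso_spacing_mm output isotropic spacing; defaults to the in-plane
#'   spacing of the input.
#' @param max_voxels resource bound on the output grid size.
#' @return An object of class `oriented_volume` with fields `density`
#'   (NA outside bone), `mask`, `spacing` (scalar, mm), `rotation`.
#' @export
apply_rotation <- function(volume, mask, rot = NULL, iso_spacing_mm = NULL,
                           max_voxels = 4e7) {
  stopifnot(inherits(volume, "calibrated_volume"), inherits(mask, "bone_mask"))
  stopifnot(all(dim(volume$values) == dim(mask$mask)))
  sp <- volume$spacing
  s <- if (is.null(iso_spacing_mm)) sp[1] else iso_spacing_mm
  if (!any(mask$mask)) stop("apply_rotation: empty mask")
  idx <- which(mask$mask, arr.ind = TRUE)
  p <- sweep(idx - 1, 2, sp, `*`)
  if (is.null(rot)) rot <- rigid_rotation(diag(3), colMeans(p))
  R <- rot$R; centre <- rot$center
  q <- sweep(p, 2, centre) %*% t(R)
  lo <- apply(q, 2, min) - 2 * s
  hi <- apply(q, 2, max) + 2 * s
  # snap the output origin so identity rotations align with the input lattice
  lo <- floor((lo + centre) / s) * s - centre
  nd <- as.integer(ceiling((hi - lo) / s)) + 1L
  if (prod(nd) > max_voxels)
    stop("resource error: rotated grid would exceed max_voxels (",
         prod(nd), " > ", max_voxels, ")")
  qx <- lo[1] + axis_coords(nd[1], s)
  qy <- lo[2] + axis_coords(nd[2], s)
  qz <- lo[3] + axis_coords(nd[3], s)
  n <- prod(nd)
  Q <- cbind(rep(qx, times = nd[2] * nd[3]),
             rep(rep(qy, each = nd[1]), times = nd[3]),
             rep(qz, each = nd[1] * nd[2]))
  P <- Q %*% R                                # R^T applied from the right
  P <- sweep(P, 2, centre, `+`)
  f <- volume$values * mask$mask              # density where bone, else 0
  occ <- mask$mask * 1
  g <- cbind(P[, 1] / sp[1], P[, 2] / sp[2], P[, 3] / sp[3])  # 0-based
  fi <- trilinear_sample(f, g)
  oi <- trilinear_sample(occ, g)
  keep <- oi >= 0.5
  dens <- rep(NA_real_, n)
  dens[keep] <- fi[keep] / oi[keep]
  structure(list(density = array(dens, nd),
                 mask = array(keep, nd),
                 spacing = s,
                 origin_mm = lo + centre,
                 rotation = rot),
            class = "oriented_volume")
}

# trilinear interpolation of array a at 0-based fractional coordinates g
# (n x 3); points outside the grid sample as 0
trilinear_sample <- function(a, g) {
  d <- dim(a)
  i0 <- floor(g)
  fr <- g - i0
  out <- numeric(nrow(g))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ii <- i0[, 1] + cx; jj <- i0[, 2] + cy; kk <- i0[, 3] + cz
    w <- (if (cx == 1) fr[, 1] else 1 - fr[, 1]) *
         (if (cy == 1) fr[, 2] else 1 - fr[, 2]) *
         (if (cz == 1) fr[, 3] else 1 - fr[, 3])
    ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3] &
      w > 0
    if (any(ok)) {
      lin <- ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok]) + 1
      out[ok] <- out[ok] + w[ok] * a[lin]
    }
  }
  out
}

#' Construct an oriented (standard-pose) volume directly
#'
#' Mostly useful for building synthetic fixtures; [apply_rotation()] is the
#' normal way to obtain one. Density values outside the mask are set to
#' `NA` (zero is a valid density inside bone).
#'
#' @param density 3D numeric array, mg/cm^3.
#' @param mask 3D logical array, same dimensions.
#' @param spacing_mm scalar isotropic voxel spacing.
#' @param origin_mm coordinate of the first voxel centre.
#' @param rotation optional [rigid_rotation()] record.
#' @export
oriented_volume <- function(density, mask, spacing_mm,
                            origin_mm = c(0, 0, 0), rotation = NULL) {
  stopifnot(is.array(density), is.logical(mask),
            all(dim(density) == dim(mask)), length(spacing_mm) == 1,
            spacing_mm > 0)
  density[!mask] <- NA_real_
  structure(list(density = density, mask = mask, spacing = spacing_mm,
                 origin_mm = origin_mm, rotation = rotation),
            class = "oriented_volume")
}

#' @export
print.oriented_volume <- function(x, ...) {
  cat(sprintf("<oriented_volume> %s voxels @ %.3f mm iso, %d bone voxels, mass %.2f g\n",
              paste(dim(x$density), collapse = " x "), x$spacing,
              sum(x$mask), oriented_mass_g(x)))
  invisible(x)
}

#' Total bone mass of an oriented volume in grams
#' @param ov an `oriented_volume`.
#' @export
oriented_mass_g <- function(ov) {
  vv <- (ov$spacing / 10)^3                    # cm^3
  sum(ov$density[ov$mask]) * vv / 1000
}

#' Total bone mass of a masked calibrated volume in grams
#' @param volume a [calibrated_volume()]; @param mask a [bone_mask()].
#' @export
masked_mass_g <- function(volume, mask) {
  sum(volume$values[mask$mask]) * voxel_volume_cm3(volume$spacing) / 1000
}
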