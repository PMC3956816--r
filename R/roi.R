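#' Compartment separation parameters
#'
#' @param cortical_threshold mg/cm^3; voxels at or above it count as
#'   cortical, below as trabecular. Default 350 mg/cm^3 (chosen in clinical
#'   use so the major compressive and tensile trabecular groupings stay
#'   trabecular while endocortical bone counts as cortical).
#' @export
compartment_params <- function(cortical_threshold = 350) {
  if (!is.finite(cortical_threshold) || cortical_threshold <= 0)
    stop("compartment_params: threshold must be > 0")
  structure(list(cortical_threshold = cortical_threshold),
            class = "compartment_params")
}

roi_names <- c("femoral_neck", "trochanter", "intertrochanter", "total_hip")

#' Automatically place the standard hip ROIs on a projection
#'
#' Landmarks are found on the background-free bone silhouette: the femoral
#' head is the largest inscribed circle in the superior part of the
#' silhouette (Euclidean distance transform); the femoral neck axis and
#' centre minimize the silhouette width among candidate lines through the
#' head-shaft corridor; the lower boundary of the intertrochanter ROI sits
#' at the lower junction of the lesser trochanter and the femoral shaft,
#' found where the medial silhouette profile returns to the shaft edge
#' below the lesser-trochanter prominence. The femoral neck box is centred
#' on the minimal-width cross-section with a default width of 15 mm along
#' the axis. Pixels medial of the neck box (femoral head) belong to no
#' ROI; the remaining silhouette above the boundary is split into
#' trochanter (lateral of the box, above the extended inferior box edge)
#' and intertrochanter. Total Hip is the exact union of the three regions.
#' Every landmark is overridable.
#'
#' @param proj a [project_coronal()] image.
#' @param neck_box_width_mm box width along the neck axis.
#' @param side `"auto"`, `"left"` or `"right"`; right hips are mirrored
#'   internally so placement is symmetric.
#' @param neck_angle_deg,neck_center_mm,boundary_z_mm,neck_halfheight_mm
#'   manual overrides (angle in degrees above the axial plane, centre in
#'   projection mm coordinates).
#' @param min_silhouette_px smallest usable silhouette.
#' @return An object of class `hip_roi_set`: integer `labels` matrix
#'   (1 neck, 2 trochanter, 3 intertrochanter, 0 none), `neck` box
#'   geometry, `boundary_z_mm`, `head` landmark, `side`.
#' @export
auto_place_rois <- function(proj, neck_box_width_mm = 15,
                            side = c("auto", "left", "right"),
                            neck_angle_deg = NULL, neck_center_mm = NULL,
                            boundary_z_mm = NULL, neck_halfheight_mm = NULL,
                            min_silhouette_px = 500) {
  stopifnot(inherits(proj, "projection_image"))
  side <- match.arg(side)
  s <- proj$spacing_mm
  o <- if (is.null(proj$origin_mm)) c(0, 0) else proj$origin_mm
  sil <- proj$mass_g > 0
  if (sum(sil) < min_silhouette_px)
    stop("landmark failure: silhouette too small (", sum(sil), " px)")
  labs2 <- EBImage::bwlabel(sil * 1)
  tab <- tabulate(labs2[labs2 > 0])
  sil <- as.array(labs2) == which.max(tab)
  if (sum(sil) < min_silhouette_px)
    stop("landmark failure: largest connected silhouette too small")
  nx <- nrow(sil); nz <- ncol(sil)
  xs <- o[1] + axis_coords(nx, s)          # absolute mm coordinates
  zs <- o[2] + axis_coords(nz, s)
  xflip <- function(v) xs[1] + xs[nx] - v
  # head: largest inscribed circle in the superior part of the silhouette
  dm <- as.array(EBImage::distmap(sil * 1))
  zr <- range(zs[colSums(sil) > 0])
  upper <- zs >= zr[1] + 0.55 * diff(zr)
  dmu <- dm; dmu[, !upper] <- 0
  hidx <- arrayInd(which.max(dmu), dim(dmu))
  head_c <- c(xs[hidx[1]], zs[hidx[2]])
  head_r <- dm[hidx[1], hidx[2]] * s
  # shaft from the inferior rows
  lowrows <- zs <= zr[1] + 0.3 * diff(zr)
  loweight <- rowSums(sil[, lowrows, drop = FALSE])
  shaft_x <- sum(xs * loweight) / sum(loweight)
  mirrored <- FALSE
  if (side == "right" || (side == "auto" && head_c[1] > shaft_x)) {
    mirrored <- TRUE
    sil <- sil[nx:1, , drop = FALSE]
    head_c[1] <- xflip(head_c[1])
    shaft_x <- xflip(shaft_x)
    if (!is.null(neck_center_mm)) neck_center_mm[1] <- xflip(neck_center_mm[1])
  }
  widths <- colSums(sil[, lowrows, drop = FALSE]) * s
  # lower quartile: insensitive to rows widened by the lesser trochanter
  halfw <- stats::quantile(widths[widths > 0], 0.25, names = FALSE) / 2
  medial_edge <- shaft_x - halfw
  sil_at <- function(x, z) {
    i <- round((x - o[1]) / s) + 1; k <- round((z - o[2]) / s) + 1
    ok <- i >= 1 & i <= nx & k >= 1 & k <= nz
    out <- logical(length(x)); out[ok] <- sil[cbind(i[ok], k[ok])]
    out
  }
  # chord width through point P perpendicular to axis direction a
  chord_width <- function(P, a) {
    n <- c(a[2], -a[1])
    if (n[2] < 0) n <- -n
    step <- s / 2
    if (!sil_at(P[1], P[2])) return(Inf)
    w <- step
    for (sgn in c(1, -1)) {
      t <- step
      while (t <= 60 && sil_at(P[1] + sgn * n[1] * t, P[2] + sgn * n[2] * t)) {
        w <- w + step; t <- t + step
      }
    }
    w
  }
  # stations march from the head centre along each candidate axis toward
  # the shaft (the anatomical neck axis passes through the head centre);
  # the minimal silhouette chord over (angle, station) defines the neck
  # cross-section. Stations inside the shaft column are excluded so
  # junction corners cannot masquerade as the isthmus.
  station_ok <- function(P) sil_at(P[1], P[2]) && P[1] < shaft_x - 0.5 * halfw
  ts <- seq(0.6 * head_r, 45, by = 1.5)
  search <- function(angles, best) {
    for (th in angles) {
      a <- c(-cos(th * pi / 180), sin(th * pi / 180)) # medial-superior
      for (t in ts) {
        P <- head_c - t * a                          # toward the shaft
        if (!station_ok(P)) next
        w <- chord_width(P, a)
        if (w < best$w) best <- list(w = w, th = th, P = P)
      }
    }
    best
  }
  best <- list(w = Inf)
  angles <- if (is.null(neck_angle_deg)) seq(8, 70, by = 2) else neck_angle_deg
  best <- search(angles, best)
  if (!is.finite(best$w)) stop("landmark failure: no neck cross-section found")
  if (is.null(neck_angle_deg)) {
    best <- search(seq(best$th - 2, best$th + 2, by = 0.5), best)
    best <- search(seq(best$th - 0.5, best$th + 0.5, by = 0.25), best)
  }
  th <- best$th
  a <- c(-cos(th * pi / 180), sin(th * pi / 180))
  n <- c(a[2], -a[1]); if (n[2] < 0) n <- -n
  if (is.null(neck_angle_deg)) {
    # the width-vs-angle profile is flat near its minimum relative to the
    # pixel quantization; sharpen the angle from the local tangents of the
    # two silhouette edges flanking the isthmus, which run parallel to the
    # neck axis
    bnd <- sil &
      !(rbind(sil[-1, , drop = FALSE], FALSE) &
          rbind(FALSE, sil[-nx, , drop = FALSE]) &
          cbind(sil[, -1, drop = FALSE], FALSE) &
          cbind(FALSE, sil[, -nz, drop = FALSE]))
    bidx <- which(bnd, arr.ind = TRUE)
    BX <- xs[bidx[, 1]]; BZ <- zs[bidx[, 2]]
    edge_dir <- function(E) {
      nearby <- (BX - E[1])^2 + (BZ - E[2])^2 <= 6^2
      if (sum(nearby) < 6) return(NULL)
      v <- eigen(stats::cov(cbind(BX[nearby], BZ[nearby])),
                 symmetric = TRUE)$vectors[, 1]
      if (sum(v * a) < 0) v <- -v
      v
    }
    dirs <- Filter(Negate(is.null),
                   lapply(list(best$P + n * best$w / 2,
                               best$P - n * best$w / 2), edge_dir))
    if (length(dirs) > 0) {
      v <- normalize3(c(rowMeans(do.call(cbind, dirs)), 0))[1:2]
      th_ref <- atan2(v[2], -v[1]) * 180 / pi
      if (is.finite(th_ref) && abs(th_ref - th) <= 15) {
        th <- th_ref
        a <- c(-cos(th * pi / 180), sin(th * pi / 180))
        n <- c(a[2], -a[1]); if (n[2] < 0) n <- -n
        best <- search(th, list(w = Inf))
        if (!is.finite(best$w))
          stop("landmark failure: no neck cross-section found")
      }
    }
  }
  # recentre on the chord midpoint
  step <- s / 2
  lo <- 0; while (lo < 60 && sil_at(best$P[1] - n[1] * (lo + step),
                                    best$P[2] - n[2] * (lo + step))) lo <- lo + step
  hi <- 0; while (hi < 60 && sil_at(best$P[1] + n[1] * (hi + step),
                                    best$P[2] + n[2] * (hi + step))) hi <- hi + step
  C <- if (is.null(neck_center_mm)) best$P + n * (hi - lo) / 2 else neck_center_mm
  hw <- neck_box_width_mm / 2
  hh <- if (is.null(neck_halfheight_mm)) 0.75 * best$w else neck_halfheight_mm
  # intertrochanter lower boundary from the medial silhouette profile:
  # scan down from the neck, past the first return to the shaft edge and
  # the lesser-trochanter prominence, to the lower junction with the shaft
  if (is.null(boundary_z_mm)) {
    medial <- rep(NA_real_, nz)
    for (k in seq_len(nz)) {
      r <- which(sil[, k]); if (length(r)) medial[k] <- xs[min(r)]
    }
    cand <- medial[zs < C[2] - hh & !is.na(medial)]
    mtab <- table(round(cand))                      # mode = shaft edge
    shaft_edge <- as.numeric(names(mtab)[which.max(mtab)])
    ks <- which(zs < C[2] & !is.na(medial))
    ks <- rev(ks)                                   # scan downward
    at_shaft <- medial[ks] >= shaft_edge - 1.0
    i1 <- which(at_shaft)[1]                        # first return to shaft
    boundary_z_mm <- zr[1]
    if (!is.na(i1)) {
      below <- ks[seq_along(ks) > i1]
      if (length(below) && any(medial[below] < shaft_edge - 1.0)) {
        ip <- below[which.min(medial[below])]       # lesser-troch prominence
        deeper <- below[below < ip & medial[below] >= shaft_edge - 1.0]
        boundary_z_mm <- if (length(deeper)) zs[max(deeper)] else zr[1]
      } else boundary_z_mm <- zs[ks[i1]]
    }
  }
  # label every silhouette pixel
  px <- which(sil, arr.ind = TRUE)
  X <- xs[px[, 1]]; Z <- zs[px[, 2]]
  sc <- (X - C[1]) * a[1] + (Z - C[2]) * a[2]       # along axis, + medial
  pc <- (X - C[1]) * n[1] + (Z - C[2]) * n[2]       # perp, + superior
  lab <- integer(nrow(px))
  above <- Z >= boundary_z_mm
  lab[above & abs(sc) <= hw & abs(pc) <= hh] <- 1L                 # neck
  free <- above & lab == 0L
  lab[free & sc < -hw & pc >= -hh] <- 2L                           # troch
  lab[above & lab == 0L & !(sc > hw & pc >= -hh)] <- 3L            # intertroch
  labels <- matrix(0L, nx, nz)
  labels[px] <- lab
  if (mirrored) {
    labels <- labels[nx:1, , drop = FALSE]
    C[1] <- xflip(C[1]); head_c[1] <- xflip(head_c[1])
  }
  structure(list(labels = labels,
                 neck = list(center_mm = C, angle_deg = th,
                             width_mm = neck_box_width_mm,
                             halfheight_mm = hh, min_width_mm = best$w),
                 boundary_z_mm = boundary_z_mm,
                 head = list(center_mm = head_c, radius_mm = head_r),
                 side = if (mirrored) "right" else "left",
                 spacing_mm = s),
            class = "hip_roi_set")
}

#' @export
print.hip_roi_set <- function(x, ...) {
  n <- tabulate(x$labels[x$labels > 0], 3)
  cat(sprintf("<hip_roi_set> neck %d px (angle %.1f deg, centre %.1f, %.1f mm), troch %d px, intertroch %d px; boundary z %.1f mm\n",
              n[1], x$neck$angle_deg, x$neck$center_mm[1], x$neck$center_mm[2],
              n[2], n[3], x$boundary_z_mm))
  invisible(x)
}

#' Measure a region of interest on a projection image
#'
#' Sums the per-pixel mass and bone path volume over the ROI pixels.
#' Area is pixel count times pixel area; areal BMD is mass/area and
#' volumetric BMD is 1000 * mass/volume.
#'
#' @param proj a `projection_image`.
#' @param pixels logical matrix (same dimensions) or 2-column index matrix
#'   selecting the ROI pixels.
#' @param roi,compartment labels recorded in the output row.
#' @return One-row data frame: `roi`, `compartment`, `abmd_gcm2`,
#'   `vbmd_mgcm3`, `mass_g`, `area_cm2`, `volume_cm3`.
#' @export
measure_roi <- function(proj, pixels, roi = "roi", compartment = "integral") {
  stopifnot(inherits(proj, "projection_image"))
  if (is.logical(pixels)) {
    stopifnot(all(dim(pixels) == dim(proj$mass_g)))
    idx <- which(pixels)
  } else idx <- pixels
  if (length(idx) == 0) stop("undefined-measure error: empty ROI")
  mass <- sum(proj$mass_g[idx])
  vol <- sum(proj$volume_cm3[idx])
  area <- length(idx) * proj$pixel_area_cm2
  data.frame(roi = roi, compartment = compartment,
             abmd_gcm2 = mass / area,
             vbmd_mgcm3 = if (vol > 0) 1000 * mass / vol else NA_real_,
             mass_g = mass, area_cm2 = area, volume_cm3 = vol)
}

#' Measure a rectangular ROI given in absolute mm coordinates
#'
#' Selects the silhouette pixels whose centres fall inside the axis-aligned
#' rectangle (absolute mm, using the projection's recorded origin) and
#' measures them; useful for comparing against analytic ground truth
#' defined in scanner coordinates.
#'
#' @param proj a `projection_image`.
#' @param x,z length-2 mm ranges.
#' @param silhouette_only drop pixels with no projected bone (default TRUE).
#' @inheritParams measure_roi
#' @export
measure_rect_roi <- function(proj, x, z, roi = "rect",
                             compartment = "integral",
                             silhouette_only = TRUE) {
  s <- proj$spacing_mm
  o <- if (is.null(proj$origin_mm)) c(0, 0) else proj$origin_mm
  xs <- o[1] + axis_coords(nrow(proj$mass_g), s)
  zs <- o[2] + axis_coords(ncol(proj$mass_g), s)
  sel <- outer(xs >= min(x) & xs <= max(x), zs >= min(z) & zs <= max(z), `&`)
  if (silhouette_only) sel <- sel & proj$mass_g > 0
  measure_roi(proj, sel, roi = roi, compartment = compartment)
}

#' Measure all standard hip ROIs
#'
#' Total Hip is measured as the exact union of femoral neck, trochanter
#' and intertrochanter (masses, areas and volumes add; aBMD is recombined
#' from the sums, not averaged).
#'
#' @param proj a `projection_image`.
#' @param rois a `hip_roi_set`.
#' @param compartment label recorded in the output rows.
#' @return A data frame with one row per ROI.
#' @export
measure_hip_rois <- function(proj, rois, compartment = "integral") {
  stopifnot(inherits(rois, "hip_roi_set"))
  rows <- lapply(1:3, function(l)
    measure_roi(proj, rois$labels == l, roi = roi_names[l],
                compartment = compartment))
  rows <- c(rows, list(measure_roi(proj, rois$labels > 0, roi = "total_hip",
                                   compartment = compartment)))
  do.call(rbind, rows)
}

#' Split the oriented volume into cortical and trabecular compartments
#'
#' Voxels at or above the cortical threshold (default 350 mg/cm^3) form
#' the cortical compartment, the rest of the bone is trabecular. Both
#' compartments are re-projected and measured per ROI; masses and volumes
#' add exactly to the integral measurements.
#'
#' @param ov an `oriented_volume`.
#' @param rois a `hip_roi_set` placed on the integral projection of `ov`.
#' @param params a [compartment_params()].
#' @return A list with `cortical_mask`/`trabecular_mask` (3D logical),
#'   `table` (data frame, one row per ROI x compartment incl. integral,
#'   with a `cortical_fraction` column on cortical rows).
#' @export
split_compartments <- function(ov, rois, params = compartment_params()) {
  stopifnot(inherits(ov, "oriented_volume"))
  dens <- ov$density
  cort <- ov$mask & !is.na(dens) & dens >= params$cortical_threshold
  trab <- ov$mask & !cort
  sub <- function(m) {
    o <- ov; o$mask <- m
    o$density[!m] <- NA_real_
    o
  }
  pi_int <- project_coronal(ov)
  pi_c <- suppressWarnings(project_coronal(sub(cort)))
  pi_t <- suppressWarnings(project_coronal(sub(trab)))
  meas <- function(proj, comp) {
    rows <- lapply(1:3, function(l) {
      px <- which(rois$labels == l)
      if (length(px) == 0) return(NULL)
      r <- measure_roi(proj, px, roi = roi_names[l], compartment = comp)
      r
    })
    tot <- measure_roi(proj, which(rois$labels > 0), roi = "total_hip",
                       compartment = comp)
    do.call(rbind, c(rows, list(tot)))
  }
  tab <- rbind(meas(pi_int, "integral"), meas(pi_c, "cortical"),
               meas(pi_t, "trabecular"))
  tab$cortical_fraction <- NA_real_
  for (rn in unique(tab$roi)) {
    mi <- tab$mass_g[tab$roi == rn & tab$compartment == "integral"]
    mc <- tab$mass_g[tab$roi == rn & tab$compartment == "cortical"]
    if (length(mi) && length(mc) && mi > 0)
      tab$cortical_fraction[tab$roi == rn & tab$compartment == "cortical"] <-
        mc / mi
  }
  list(cortical_mask = cort, trabecular_mask = trab, table = tab,
       threshold = params$cortical_threshold)
}
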