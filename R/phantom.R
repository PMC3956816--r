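#' Digital proximal-femur phantom specification
#'
#' Constructive-solid-geometry description of a stylized left proximal femur
#' in the standard pose (shaft vertical, neck axis in the x-z plane pointing
#' medially), plus an in-scan calibration rod insert. The phantom has
#' analytic ground truth, so the whole analysis pipeline can be exercised
#' and checked without any real scan.
#'
#' The bone is the union of four primitives: a shaft cylinder (vertical), a
#' neck cylinder tilted by the neck-shaft angle, a head sphere at the distal
#' end of the neck, and a lesser-trochanter sphere on the medial shaft
#' surface. Each point within `cortical_thickness_mm` of the union surface
#' is "cortical", deeper points are "trabecular". Everything else is
#' water-equivalent soft tissue except the calibration rods.
#'
#' @param head_radius_mm head sphere radius.
#' @param neck_radius_mm,neck_length_mm neck cylinder radius/length.
#' @param neck_shaft_angle_deg angle between shaft axis and neck axis
#'   (anatomically ~125-135 degrees; the neck elevation above the axial
#'   plane is `angle - 90`).
#' @param shaft_radius_mm,shaft_length_mm shaft cylinder radius/length.
#' @param troch_radius_mm lesser-trochanter sphere radius.
#' @param cortical_thickness_mm cortical shell thickness.
#' @param cortical_density,trabecular_density,background_density mg/cm^3
#'   equivalent K2HPO4 densities of the compartments.
#' @param rods [rod_layout()] of the calibration insert.
#' @param noise_sd_hu Gaussian noise SD added to the HU volume.
#' @param slope,intercept true calibration: density = slope * HU + intercept.
#' @param spacing voxel spacing (mm).
#' @param extent_mm physical grid extent (mm) along x, y, z.
#' @param supersample partial-volume supersampling factor per axis.
#' @param seed RNG seed for the noise (determinism contract).
#' @return An object of class `femur_spec`.
#' @export
digital_femur_spec <- function(head_radius_mm = 21,
                               neck_radius_mm = 12.5,
                               neck_length_mm = 38,
                               neck_shaft_angle_deg = 130,
                               shaft_radius_mm = 14,
                               shaft_length_mm = 70,
                               troch_radius_mm = 9,
                               cortical_thickness_mm = 3,
                               cortical_density = 800,
                               trabecular_density = 150,
                               background_density = 0,
                               rods = default_rod_layout(),
                               noise_sd_hu = 0,
                               slope = 1.25,
                               intercept = -8,
                               spacing = c(0.781, 0.781, 3.0),
                               extent_mm = c(100, 80, 126),
                               supersample = 3L,
                               seed = 1L) {
  stopifnot(head_radius_mm > 0, neck_radius_mm > 0, shaft_radius_mm > 0,
            troch_radius_mm > 0, cortical_thickness_mm > 0,
            is.finite(cortical_density), is.finite(trabecular_density),
            cortical_density > trabecular_density,
            slope > 0, all(spacing > 0), supersample >= 1)
  spec <- list(head_radius_mm = head_radius_mm,
               neck_radius_mm = neck_radius_mm,
               neck_length_mm = neck_length_mm,
               neck_shaft_angle_deg = neck_shaft_angle_deg,
               shaft_radius_mm = shaft_radius_mm,
               shaft_length_mm = shaft_length_mm,
               troch_radius_mm = troch_radius_mm,
               cortical_thickness_mm = cortical_thickness_mm,
               cortical_density = cortical_density,
               trabecular_density = trabecular_density,
               background_density = background_density,
               rods = rods,
               noise_sd_hu = noise_sd_hu,
               slope = slope, intercept = intercept,
               spacing = as.numeric(spacing),
               extent_mm = as.numeric(extent_mm),
               supersample = as.integer(supersample),
               seed = as.integer(seed))
  class(spec) <- "femur_spec"
  geom <- femur_geometry(spec)
  ex <- spec$extent_mm
  hi <- c(max(geom$head_c[1] + head_radius_mm,
              geom$shaft_c[1] + shaft_radius_mm,
              geom$troch_c[1] + troch_radius_mm),
          geom$shaft_c[2] + shaft_radius_mm,
          geom$head_c[3] + head_radius_mm)
  lo <- c(min(geom$head_c[1] - head_radius_mm,
              geom$shaft_c[1] - shaft_radius_mm,
              geom$troch_c[1] - troch_radius_mm),
          geom$shaft_c[2] - shaft_radius_mm,
          geom$shaft_z[1] - 1)
  if (any(lo < 0) || any(hi > ex))
    stop("geometry error: phantom geometry exceeds the grid extent")
  spec
}

# Derived primitive parameters (mm, standard pose). Shaft axis vertical at
# (30, 40); neck rises medially (toward +x, the standard-pose direction of
# the neck's in-plane component) from the shaft top.
femur_geometry <- function(spec) {
  shaft_c <- c(30, 40)
  shaft_z <- c(15, 15 + spec$shaft_length_mm)
  elev <- (spec$neck_shaft_angle_deg - 90) * pi / 180
  neck_a <- c(cos(elev), 0, sin(elev))
  neck_b <- c(shaft_c[1], shaft_c[2], shaft_z[2] - 10)
  head_c <- neck_b + spec$neck_length_mm * neck_a
  troch_c <- c(shaft_c[1] + spec$shaft_radius_mm, shaft_c[2], shaft_z[1] + 15)
  list(shaft_c = shaft_c, shaft_z = shaft_z,
       neck_a = neck_a, neck_b = neck_b, neck_len = spec$neck_length_mm,
       head_c = head_c, troch_c = troch_c)
}

#' Default calibration rod insert for the digital phantom
#'
#' Three parallel K2HPO4-equivalent rods posterior to the femur, spanning
#' most of the axial range, with a few millimetres of soft-tissue clearance
#' from the bone so phantom and femur never merge into one connected
#' component. Densities 0 (water blank), 100 and 200 mg/cm^3; the
#' 200 mg/cm^3 rod doubles as the QA reference.
#'
#' @param x,y rod centre coordinates (mm) in the axial plane.
#' @param radius_mm rod radius.
#' @param densities nominal equivalent densities mg/cm^3.
#' @param z_range_mm axial range over which the rods are visible.
#' @export
default_rod_layout <- function(x = c(30, 50, 70), y = c(70, 70, 70),
                               radius_mm = 6, densities = c(0, 100, 200),
                               z_range_mm = c(6, 120)) {
  rod_layout(x = x, y = y, radius_mm = radius_mm, densities = densities,
             z_range_mm = z_range_mm)
}

# ---- signed distance functions; p is an n x 3 matrix of mm coordinates ----

sdf_sphere <- function(p, c0, r) {
  sqrt((p[, 1] - c0[1])^2 + (p[, 2] - c0[2])^2 + (p[, 3] - c0[3])^2) - r
}

# capped cylinder, base point b, unit axis a, length L, radius r
sdf_capped_cylinder <- function(p, b, a, L, r) {
  qx <- p[, 1] - b[1]; qy <- p[, 2] - b[2]; qz <- p[, 3] - b[3]
  t <- qx * a[1] + qy * a[2] + qz * a[3]
  rad2 <- pmax(qx^2 + qy^2 + qz^2 - t^2, 0)
  dr <- sqrt(rad2) - r
  dz <- pmax(-t, t - L)
  inside <- pmax(dr, dz)
  out <- sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2)
  ifelse(dr > 0 | dz > 0, out, inside)
}

# signed distance to the bone union at points p
femur_sdf <- function(p, spec, geom = femur_geometry(spec)) {
  d <- sdf_capped_cylinder(p, c(geom$shaft_c[1], geom$shaft_c[2], geom$shaft_z[1]),
                           c(0, 0, 1), diff(geom$shaft_z), spec$shaft_radius_mm)
  d <- pmin(d, sdf_capped_cylinder(p, geom$neck_b, geom$neck_a, geom$neck_len,
                                   spec$neck_radius_mm))
  d <- pmin(d, sdf_sphere(p, geom$head_c, spec$head_radius_mm))
  pmin(d, sdf_sphere(p, geom$troch_c, spec$troch_radius_mm))
}

# density (mg/cm^3) at points p: bone shell/core, rods, background
femur_density <- function(p, spec, geom = femur_geometry(spec)) {
  d <- femur_sdf(p, spec, geom)
  dens <- rep(spec$background_density, nrow(p))
  rods <- spec$rods
  for (i in seq_len(nrow(rods$rods))) {
    r <- rods$rods[i, ]
    inrod <- (p[, 1] - r$x)^2 + (p[, 2] - r$y)^2 <= r$radius_mm^2 &
      p[, 3] >= rods$z_range_mm[1] & p[, 3] <= rods$z_range_mm[2]
    dens[inrod] <- r$density
  }
  cort <- d <= 0 & d > -spec$cortical_thickness_mm
  trab <- d <= -spec$cortical_thickness_mm
  dens[cort] <- spec$cortical_density
  dens[trab] <- spec$trabecular_density
  attr(dens, "bone") <- d <= 0
  dens
}

# average a fine (ss*n1) x (ss*n2) matrix into n1 x n2 voxel means
pool2 <- function(m, ss, n1, n2) {
  dim(m) <- c(ss, n1, ss * n2)
  m <- colMeans(m)                      # n1 x (ss*n2)
  dim(m) <- c(n1, ss, n2)
  m <- aperm(m, c(2, 1, 3))
  dim(m) <- c(ss, n1 * n2)
  matrix(colMeans(m), n1, n2)
}

#' Generate a synthetic CT volume of the digital femur phantom
#'
#' Rasterizes the analytic phantom with supersampled partial-volume
#' averaging, converts density to HU through the inverse of the true
#' calibration, and adds Gaussian noise. Deterministic for a given seed.
#'
#' @param spec a [digital_femur_spec()].
#' @return A list with components `hu` ([ct_volume()], noisy),
#'   `density` ([calibrated_volume()], noiseless ground truth),
#'   `mask` ([bone_mask()], supersampled occupancy >= 0.5) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "femur_spec"))
  geom <- femur_geometry(spec)
  sp <- spec$spacing; ss <- spec$supersample
  dims <- as.integer(floor(spec$extent_mm / sp)) + 1L
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  # supersample offsets within a voxel, per axis
  off <- function(h) ((seq_len(ss) - 0.5) / ss - 0.5) * h
  xf <- rep(axis_coords(nx, sp[1]), each = ss) + rep(off(sp[1]), nx)
  yf <- rep(axis_coords(ny, sp[2]), each = ss) + rep(off(sp[2]), ny)
  zo <- off(sp[3])
  dens <- array(0, dims)
  occ <- array(0, dims)
  pxy <- cbind(rep(xf, times = length(yf)), rep(yf, each = length(xf)))
  for (k in seq_len(nz)) {
    zc <- (k - 1) * sp[3]
    dslice <- matrix(0, length(xf), length(yf))
    oslice <- matrix(0, length(xf), length(yf))
    for (dz in zo) {
      p <- cbind(pxy, zc + dz)
      dv <- femur_density(p, spec, geom)
      dslice <- dslice + dv / ss
      oslice <- oslice + attr(dv, "bone") / ss
    }
    dens[, , k] <- pool2(dslice, ss, nx, ny)
    occ[, , k] <- pool2(oslice, ss, nx, ny)
  }
  hu <- (dens - spec$intercept) / spec$slope
  if (spec$noise_sd_hu > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(spec$seed)
    hu <- hu + array(stats::rnorm(length(hu), 0, spec$noise_sd_hu), dim(hu))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  list(hu = ct_volume(hu, sp),
       density = calibrated_volume(dens, sp),
       mask = bone_mask(occ >= 0.5, sp),
       spec = spec)
}

#' Exact projection oracle for the digital phantom
#'
#' Computes per-ROI projected mass, area, volume, areal BMD and cortical
#' fraction directly from the analytic geometry, independently of the
#' voxel pipeline. Because every phantom primitive has its axis in the
#' coronal mid-plane, the anteroposterior chord through the bone at a given
#' (x, z) is a single interval whose length is known in closed form; the
#' remaining x-z integration is numeric on a fine grid (`factor` times
#' finer than the acquisition grid).
#'
#' @param spec a [digital_femur_spec()].
#' @param roi either `NULL` (whole silhouette) or a list with elements
#'   `x = c(lo, hi)` and `z = c(lo, hi)` in mm.
#' @param factor in-plane refinement factor relative to `spec$spacing[1]`.
#' @return A list: `mass_g`, `area_cm2`, `volume_cm3`, `abmd_gcm2`,
#'   `cortical_mass_g`, `trabecular_mass_g`, `cortical_fraction`.
#' @export
oracle_projection <- function(spec, roi = NULL, factor = 10) {
  stopifnot(inherits(spec, "femur_spec"), factor >= 1)
  geom <- femur_geometry(spec)
  h <- spec$spacing[1] / factor
  xr <- if (is.null(roi)) c(0, spec$extent_mm[1]) else sort(roi$x)
  zr <- if (is.null(roi)) c(0, spec$extent_mm[3]) else sort(roi$z)
  xs <- seq(xr[1] + h / 2, xr[2], by = h)
  zs <- seq(zr[1] + h / 2, zr[2], by = h)
  X <- rep(xs, times = length(zs))
  Z <- rep(zs, each = length(xs))

  # AP half-chord through one primitive, possibly eroded by `er`
  half_sphere <- function(c0, r, er) {
    rr <- r - er
    w2 <- rr^2 - (X - c0[1])^2 - (Z - c0[3])^2
    sqrt(pmax(w2, 0))
  }
  half_vcyl <- function(cx, z0, z1, r, er) {
    w2 <- (r - er)^2 - (X - cx)^2
    w <- sqrt(pmax(w2, 0))
    w[Z < z0 + er | Z > z1 - er] <- 0
    w
  }
  half_neck <- function(b, a, L, r, er) {
    t <- (X - b[1]) * a[1] + (Z - b[3]) * a[3]
    q2 <- (X - b[1])^2 + (Z - b[3])^2 - t^2
    w2 <- (r - er)^2 - q2
    w <- sqrt(pmax(w2, 0))
    w[t < er | t > L - er] <- 0
    w
  }
  halfwidth <- function(er) {
    w <- half_vcyl(geom$shaft_c[1], geom$shaft_z[1], geom$shaft_z[2],
                   spec$shaft_radius_mm, er)
    w <- pmax(w, half_neck(geom$neck_b, geom$neck_a, geom$neck_len,
                           spec$neck_radius_mm, er))
    w <- pmax(w, half_sphere(geom$head_c, spec$head_radius_mm, er))
    pmax(w, half_sphere(geom$troch_c, spec$troch_radius_mm, er))
  }
  Lb <- 2 * halfwidth(0)                         # bone chord, mm
  Lt <- 2 * halfwidth(spec$cortical_thickness_mm) # trabecular chord, mm
  Lc <- Lb - Lt
  px_cm2 <- (h / 10)^2
  mass_c <- sum(spec$cortical_density * Lc / 10) * px_cm2 / 1000   # g
  mass_t <- sum(spec$trabecular_density * Lt / 10) * px_cm2 / 1000
  area <- sum(Lb > 0) * px_cm2
  vol <- sum(Lb / 10) * px_cm2
  mass <- mass_c + mass_t
  list(mass_g = mass, area_cm2 = area, volume_cm3 = vol,
       abmd_gcm2 = if (area > 0) mass / area else 0,
       cortical_mass_g = mass_c, trabecular_mass_g = mass_t,
       cortical_fraction = if (mass > 0) mass_c / mass else NA_real_)
}

#' Simulate a longitudinal precision cohort
#'
#' Hierarchical normal model emulating a stable (non-losing) cohort measured
#' at yearly visits: patient true means are drawn around the population
#' mean, visit values add an optional per-visit drift and within-patient
#' measurement noise.
#'
#' @param n_patients number of patients.
#' @param visits visits per patient (scalar or per-patient vector).
#' @param mean population mean BMD g/cm^2.
#' @param between_sd between-patient SD g/cm^2.
#' @param within_sd within-patient (measurement) SD g/cm^2.
#' @param drift additive change per visit g/cm^2.
#' @param seed RNG seed; draws are deterministic per seed.
#' @return A data frame with columns `patient_id`, `visit`, `bmd`.
#' @export
generate_longitudinal_cohort <- function(n_patients = 22, visits = 3,
                                         mean = 0.647, between_sd = 0.08,
                                         within_sd = 0.012, drift = 0,
                                         seed = 1L) {
  stopifnot(between_sd >= 0, within_sd >= 0, n_patients >= 1)
  visits <- rep_len(visits, n_patients)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  pm <- stats::rnorm(n_patients, mean, between_sd)
  rows <- do.call(rbind, lapply(seq_len(n_patients), function(i) {
    v <- seq_len(visits[i])
    data.frame(patient_id = sprintf("P%03d", i), visit = v,
               bmd = pm[i] + drift * (v - 1) +
                 stats::rnorm(visits[i], 0, within_sd))
  }))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  rows
}
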