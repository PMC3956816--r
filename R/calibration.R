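#' Calibration rod layout
#'
#' In-plane positions, radii and nominal equivalent K2HPO4 densities of the
#' calibration rods visible in the scan, plus the axial range over which
#' they can be sampled.
#'
#' @param x,y rod centre coordinates (mm).
#' @param radius_mm rod radius (scalar or per-rod), mm.
#' @param densities nominal equivalent densities, mg/cm^3. At least two
#'   distinct values are required for a calibration fit.
#' @param z_range_mm length-2 axial range (mm) over which rods are sampled.
#' @return An object of class `rod_layout`.
#' @export
rod_layout <- function(x, y, radius_mm, densities, z_range_mm) {
  n <- length(x)
  stopifnot(length(y) == n, length(densities) == n, n >= 1)
  radius_mm <- rep_len(radius_mm, n)
  if (any(radius_mm <= 0)) stop("rod_layout: radii must be positive")
  z_range_mm <- sort(as.numeric(z_range_mm))
  structure(list(rods = data.frame(x = x, y = y, radius_mm = radius_mm,
                                   density = densities),
                 z_range_mm = z_range_mm),
            class = "rod_layout")
}

#' Read/write a rod layout as YAML or JSON
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @export
read_rod_layout <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  rod_layout(x = obj$x, y = obj$y, radius_mm = obj$radius_mm,
             densities = obj$densities, z_range_mm = obj$z_range_mm)
}

#' @param layout a [rod_layout()].
#' @rdname read_rod_layout
#' @export
write_rod_layout <- function(layout, path) {
  obj <- list(x = layout$rods$x, y = layout$rods$y,
              radius_mm = layout$rods$radius_mm,
              densities = layout$rods$density,
              z_range_mm = layout$z_range_mm)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# mean value over an eroded rod disk (radius * shrink) across the layout's
# slice range; `vol` may be a ct_volume or calibrated_volume
rod_mean <- function(vol, rod, z_range_mm, shrink = 0.7) {
  sp <- vol$spacing; dims <- dim(vol$values)
  r <- rod$radius_mm * shrink
  xs <- axis_coords(dims[1], sp[1]); ys <- axis_coords(dims[2], sp[2])
  ii <- which(abs(xs - rod$x) <= r)
  jj <- which(abs(ys - rod$y) <= r)
  if (rod$x - r < -sp[1] / 2 || rod$x + r > max(xs) + sp[1] / 2 ||
      rod$y - r < -sp[2] / 2 || rod$y + r > max(ys) + sp[2] / 2)
    stop("geometry error: calibration rod lies outside the grid")
  zc <- axis_coords(dims[3], sp[3])
  # erode the slice range by half a slice to skip partial-volume end slices
  kk <- which(zc >= z_range_mm[1] + sp[3] / 2 & zc <= z_range_mm[2] - sp[3] / 2)
  if (length(kk) == 0)
    kk <- which(zc >= z_range_mm[1] & zc <= z_range_mm[2])
  if (length(kk) == 0) stop("geometry error: rod slice range outside volume")
  indisk <- outer(xs[ii] - rod$x, ys[jj] - rod$y,
                  function(a, b) a^2 + b^2 <= r^2)
  if (!any(indisk)) stop("geometry error: eroded rod disk contains no voxel")
  sub <- vol$values[ii, jj, kk, drop = FALSE]
  dim(sub) <- c(length(ii) * length(jj), length(kk))
  mean(colMeans(sub[as.vector(indisk), , drop = FALSE]))
}

#' Fit the HU-to-density calibration from the rod phantom
#'
#' Samples each rod over an eroded disk (70% of the nominal radius, to
#' avoid partial-volume rims) averaged across the layout's slice range,
#' then fits an ordinary least-squares line mapping mean rod HU to nominal
#' equivalent density. The beam-hardening factor is initialized to 1
#' (no correction); see [qa_check()].
#'
#' @param volume a [ct_volume()] containing the rods.
#' @param layout a [rod_layout()] with at least two distinct densities.
#' @return An object of class `calibration_fit` with fields `slope`
#'   (mg/cm^3 per HU), `intercept` (mg/cm^3), `residuals` (per rod,
#'   mg/cm^3), `rod_hu`, `beam_hardening_factor`.
#' @export
fit_calibration <- function(volume, layout) {
  stopifnot(inherits(volume, "ct_volume"), inherits(layout, "rod_layout"))
  if (length(unique(layout$rods$density)) < 2)
    stop("degenerate-fit error: need >= 2 rods with distinct nominal densities")
  hu <- vapply(seq_len(nrow(layout$rods)), function(i)
    rod_mean(volume, layout$rods[i, ], layout$z_range_mm), numeric(1))
  dens <- layout$rods$density
  fit <- stats::lm(dens ~ hu)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("degenerate-fit error: non-positive calibration slope")
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 residuals = unname(stats::residuals(fit)),
                 rod_hu = hu,
                 nominal = dens,
                 beam_hardening_factor = 1.0),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> density = %.4f * HU %+.2f mg/cm3 (BH factor %.4f)\n",
              x$slope, x$intercept, x$beam_hardening_factor))
  cat(sprintf("  rods: HU %s -> nominal %s, residual RMS %.3f mg/cm3\n",
              paste(sprintf("%.1f", x$rod_hu), collapse = ", "),
              paste(sprintf("%.0f", x$nominal), collapse = ", "),
              sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Apply a calibration fit to a CT volume
#'
#' Elementwise affine map `density = slope * beam_hardening_factor * HU +
#' intercept`; spacing is preserved.
#'
#' @param volume a [ct_volume()].
#' @param fit a `calibration_fit`.
#' @return A [calibrated_volume()] in mg/cm^3 equivalent K2HPO4.
#' @export
apply_calibration <- function(volume, fit) {
  stopifnot(inherits(volume, "ct_volume"), inherits(fit, "calibration_fit"))
  stopifnot(fit$slope > 0, fit$beam_hardening_factor > 0)
  calibrated_volume(fit$slope * fit$beam_hardening_factor * volume$values +
                      fit$intercept,
                    spacing = volume$spacing, fit = fit)
}

#' Quality-assurance check against the 200 mg/cm^3 reference
#'
#' Measures the calibrated density of the QA reference rod (nominal
#' 200.0 mg/cm^3 aqueous K2HPO4 by default), reports the percent deviation
#' and a suggested beam-hardening slope-correction factor
#' `nominal / measured`. The suggestion is reported, never auto-applied;
#' pass `apply_correction = TRUE` to receive an updated fit.
#'
#' @param qa_volume a [ct_volume()] of the QA scan.
#' @param layout a [rod_layout()]; the reference rod is the one whose
#'   nominal density equals `nominal` (within 0.5 mg/cm^3).
#' @param fit the `calibration_fit` under test.
#' @param nominal reference density, mg/cm^3.
#' @param tolerance_pct pass tolerance on |percent deviation|.
#' @param apply_correction if TRUE, the returned object carries
#'   `corrected_fit` with the suggested factor applied.
#' @return An object of class `qa_result`.
#' @export
qa_check <- function(qa_volume, layout, fit, nominal = 200.0,
                     tolerance_pct = 2, apply_correction = FALSE) {
  stopifnot(inherits(qa_volume, "ct_volume"), inherits(fit, "calibration_fit"))
  idx <- which(abs(layout$rods$density - nominal) < 0.5)
  if (length(idx) == 0)
    stop("geometry error: no QA reference rod with nominal density ", nominal)
  cal <- apply_calibration(qa_volume, fit)
  measured <- rod_mean(cal, layout$rods[idx[1], ], layout$z_range_mm)
  dev <- 100 * (measured - nominal) / nominal
  factor <- nominal / measured
  res <- list(measured_reference_density = measured,
              nominal_reference_density = nominal,
              percent_deviation = dev,
              tolerance_pct = tolerance_pct,
              pass = abs(dev) <= tolerance_pct,
              suggested_beam_hardening_factor = factor)
  if (apply_correction) {
    cf <- fit
    cf$beam_hardening_factor <- fit$beam_hardening_factor * factor
    res$corrected_fit <- cf
  }
  structure(res, class = "qa_result")
}

#' @export
print.qa_result <- function(x, ...) {
  cat(sprintf("<qa_result> measured %.2f vs nominal %.1f mg/cm3: %+.2f%% [%s at +/-%.1f%%]\n",
              x$measured_reference_density, x$nominal_reference_density,
              x$percent_deviation, if (x$pass) "PASS" else "FAIL",
              x$tolerance_pct))
  cat(sprintf("  suggested beam-hardening slope factor: %.4f\n",
              x$suggested_beam_hardening_factor))
  invisible(x)
}
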