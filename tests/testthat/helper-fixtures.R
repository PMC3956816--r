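# Shared fixtures, built once per session. The digital femur phantom and
# its pipeline products are cached because several files exercise them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

default_spec <- function(...) digital_femur_spec(...)

default_box <- function(vol) {
  voxel_box_mm(c(5, 5, 3), c(95, 63, 123), vol$spacing, dim(vol))
}

phantom_fixture <- function() {
  fixture("phantom", function() generate_phantom(default_spec()))
}

# calibrated volume + filled mask of the default phantom
pipeline_fixture <- function() {
  fixture("pipeline", function() {
    ph <- phantom_fixture()
    fit <- fit_calibration(ph$hu, ph$spec$rods)
    cal <- apply_calibration(ph$hu, fit)
    box <- default_box(cal)
    mask <- fill_cortical_envelope(segment_bone(cal, box), box)
    rot <- estimate_standard_rotation(mask, cal)
    ov <- apply_rotation(cal, mask, rot)
    proj <- project_coronal(ov)
    rois <- auto_place_rois(proj)
    list(ph = ph, fit = fit, cal = cal, box = box, mask = mask,
         rot = rot, ov = ov, proj = proj, rois = rois)
  })
}

# small calibration test volume: vertical rods of constant HU in a zero
# background
rod_test_volume <- function(hu, layout, dims = c(60, 40, 5),
                            spacing = c(1, 1, 2), background = 0) {
  vals <- array(background, dims)
  xs <- (seq_len(dims[1]) - 1) * spacing[1]
  ys <- (seq_len(dims[2]) - 1) * spacing[2]
  for (i in seq_len(nrow(layout$rods))) {
    r <- layout$rods[i, ]
    disk <- outer(xs - r$x, ys - r$y, function(a, b) a^2 + b^2 <= r$radius_mm^2)
    for (k in seq_len(dims[3])) {
      sl <- vals[, , k]
      sl[disk] <- hu[i]
      vals[, , k] <- sl
    }
  }
  ct_volume(vals, spacing)
}

three_rod_layout <- function(dens = c(0, 100, 200)) {
  rod_layout(x = c(10, 28, 46), y = c(20, 20, 20), radius_mm = 5,
             densities = dens, z_range_mm = c(0, 8))
}

# analytic solid cylinder (axis along z) rasterized without partial volume
cylinder_volume <- function(dims = c(40, 40, 20), spacing = c(1, 1, 1),
                            centre = c(20, 20), radius = 12,
                            inside = 800, outside = 0) {
  xs <- (seq_len(dims[1]) - 1) * spacing[1]
  ys <- (seq_len(dims[2]) - 1) * spacing[2]
  disk <- outer(xs - centre[1], ys - centre[2],
                function(a, b) a^2 + b^2 <= radius^2)
  vals <- array(outside, dims)
  for (k in seq_len(dims[3])) {
    sl <- vals[, , k]; sl[disk] <- inside; vals[, , k] <- sl
  }
  list(vol = calibrated_volume(vals, spacing), disk = disk)
}

# hand-coded OLS via normal equations: the independent regression oracle
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  res <- y - slope * x - intercept
  list(slope = slope, intercept = intercept,
       r = sum((x - mean(x)) * (y - mean(y))) /
         sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
       see = sqrt(sum(res^2) / (n - 2)))
}

# hand-coded Welch statistic: the independent t-test oracle
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
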