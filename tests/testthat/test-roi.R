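test_that("uniform slab ROI reproduces the closed-form measures", {
  # slab: 1000 mg/cm3, 10 mm AP thickness, 50 x 20 mm face = 10 cm2
  s <- 1
  dims <- c(52, 12, 22)
  dens <- array(NA_real_, dims); m <- array(FALSE, dims)
  dens[2:51, 2:11, 2:21] <- 1000; m[2:51, 2:11, 2:21] <- TRUE
  pr <- project_coronal(oriented_volume(dens, m, s))
  sel <- pr$mass_g > 0
  r <- measure_roi(pr, sel)
  expect_equal(r$abmd_gcm2, 1.0, tolerance = 1e-12)
  expect_equal(r$vbmd_mgcm3, 1000, tolerance = 1e-12)
  expect_equal(r$mass_g, 10, tolerance = 1e-12)
  expect_equal(r$area_cm2, 10, tolerance = 1e-12)
  expect_equal(r$volume_cm3, 10, tolerance = 1e-12)
  expect_error(measure_roi(pr, pr$mass_g < 0), "undefined-measure")
})

test_that("ROI sums match a brute-force per-pixel oracle", {
  set.seed(11)
  d <- c(10, 8, 10)
  dens <- array(runif(prod(d), 0, 900), d)
  m <- array(runif(prod(d)) < 0.5, d)
  pr <- suppressWarnings(project_coronal(oriented_volume(dens, m, 0.7)))
  sel <- matrix(runif(100) < 0.5, 10, 10) & pr$mass_g > 0
  if (any(sel)) {
    r <- measure_roi(pr, sel)
    expect_equal(r$mass_g, sum(pr$mass_g[sel]), tolerance = 1e-12)
    expect_equal(r$volume_cm3, sum(pr$volume_cm3[sel]), tolerance = 1e-12)
    expect_equal(r$area_cm2, sum(sel) * pr$pixel_area_cm2, tolerance = 1e-12)
  }
})

test_that("auto placement recovers the generating neck geometry", {
  pl <- pipeline_fixture()
  spec <- pl$ph$spec
  geom <- ctxa:::femur_geometry(spec)
  elev_true <- spec$neck_shaft_angle_deg - 90
  expect_lt(abs(pl$rois$neck$angle_deg - elev_true), 5)
  # box centre within 5 mm of the generating neck axis
  C <- pl$rois$neck$center_mm
  b <- geom$neck_b[c(1, 3)]; a2 <- geom$neck_a[c(1, 3)]
  rel <- C - b
  expect_lt(abs(rel[1] * a2[2] - rel[2] * a2[1]), 5)   # distance to axis
  # head landmark near the generating head sphere
  expect_lt(sqrt(sum((pl$rois$head$center_mm - geom$head_c[c(1, 3)])^2)), 5)
  expect_lt(abs(pl$rois$head$radius_mm - spec$head_radius_mm), 3)
  # intertrochanter boundary near the lesser trochanter-shaft junction
  junction <- geom$troch_c[3] - spec$troch_radius_mm
  expect_lt(abs(pl$rois$boundary_z_mm - junction), 5)
})

test_that("ROIs are pairwise disjoint and total hip is their exact union", {
  pl <- pipeline_fixture()
  lab <- pl$rois$labels
  tab <- measure_hip_rois(pl$proj, pl$rois)
  expect_equal(sum(lab == 1) + sum(lab == 2) + sum(lab == 3), sum(lab > 0))
  i3 <- match(c("femoral_neck", "trochanter", "intertrochanter"), tab$roi)
  it <- match("total_hip", tab$roi)
  expect_equal(sum(tab$mass_g[i3]), tab$mass_g[it], tolerance = 1e-12)
  expect_equal(sum(tab$area_cm2[i3]), tab$area_cm2[it], tolerance = 1e-12)
  expect_equal(sum(tab$volume_cm3[i3]), tab$volume_cm3[it], tolerance = 1e-12)
  # aBMD recombined from sums, not averaged
  expect_equal(tab$abmd_gcm2[it], tab$mass_g[it] / tab$area_cm2[it])
})

test_that("mirrored projections give identical ROI areas", {
  pl <- pipeline_fixture()
  pr <- pl$proj
  flip <- function(mat) mat[nrow(mat):1, , drop = FALSE]
  pr2 <- pr
  pr2$mass_g <- flip(pr$mass_g); pr2$volume_cm3 <- flip(pr$volume_cm3)
  pr2$abmd_gcm2 <- flip(pr$abmd_gcm2); pr2$pathlength_cm <- flip(pr$pathlength_cm)
  r1 <- auto_place_rois(pr)
  r2 <- auto_place_rois(pr2)
  expect_equal(r2$side != r1$side, TRUE)
  expect_identical(tabulate(r1$labels[r1$labels > 0], 3),
                   tabulate(r2$labels[r2$labels > 0], 3))
})

test_that("blank or tiny projections raise a landmark failure", {
  pr <- suppressWarnings(project_coronal(oriented_volume(
    array(NA_real_, c(30, 5, 30)), array(FALSE, c(30, 5, 30)), 1)))
  expect_error(auto_place_rois(pr), "landmark failure")
})

test_that("compartment split conserves mass/volume and responds to threshold", {
  pl <- pipeline_fixture()
  comp <- split_compartments(pl$ov, pl$rois)
  tab <- comp$table
  for (rn in unique(tab$roi)) {
    gi <- function(cp) tab[tab$roi == rn & tab$compartment == cp, ]
    expect_equal(gi("cortical")$mass_g + gi("trabecular")$mass_g,
                 gi("integral")$mass_g, tolerance = 1e-12)
    expect_equal(gi("cortical")$volume_cm3 + gi("trabecular")$volume_cm3,
                 gi("integral")$volume_cm3, tolerance = 1e-12)
  }
  # cortical fraction decreases as the threshold rises
  fr <- sapply(c(200, 350, 600), function(th) {
    ct <- split_compartments(pl$ov, pl$rois, compartment_params(th))$table
    ct$cortical_fraction[ct$roi == "total_hip" & ct$compartment == "cortical"]
  })
  expect_true(all(diff(fr) <= 0))
  # near-zero threshold: everything positive is cortical
  c0 <- split_compartments(pl$ov, pl$rois, compartment_params(1e-9))$table
  expect_equal(c0$cortical_fraction[c0$roi == "total_hip" &
                                      c0$compartment == "cortical"], 1,
               tolerance = 1e-12)
})

test_that("uniformly dense bone is entirely cortical at the default threshold", {
  dims <- c(20, 10, 20)
  dens <- array(NA_real_, dims); m <- array(FALSE, dims)
  dens[5:15, 2:9, 5:15] <- 800; m[5:15, 2:9, 5:15] <- TRUE
  ov <- oriented_volume(dens, m, 1)
  pr <- project_coronal(ov)
  rois <- structure(list(labels = matrix(as.integer(pr$mass_g > 0) * 3L,
                                         dims[1], dims[3]),
                         spacing_mm = 1),
                    class = "hip_roi_set")
  comp <- split_compartments(ov, rois)
  tt <- comp$table
  expect_equal(tt$mass_g[tt$compartment == "trabecular" &
                           tt$roi == "intertrochanter"], 0)
  expect_equal(tt$cortical_fraction[tt$compartment == "cortical" &
                                      tt$roi == "intertrochanter"], 1)
})

test_that("cortical fraction matches the analytic shell-core oracle within 3%", {
  pl <- pipeline_fixture()
  comp <- split_compartments(pl$ov, pl$rois)
  tt <- comp$table
  pipe_fr <- tt$cortical_fraction[tt$roi == "total_hip" &
                                    tt$compartment == "cortical"]
  orc <- oracle_projection(pl$ph$spec)
  expect_lt(abs(pipe_fr - orc$cortical_fraction), 0.03)
})
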