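test_that("background-only regions have constant HU from the inverse calibration", {
  ph <- phantom_fixture()
  spec <- ph$spec
  # a corner region far from bone and rods
  hu <- ph$hu$values[1:5, 1:5, 1:5]
  expect_true(all(abs(hu - (spec$background_density - spec$intercept) /
                        spec$slope) < 1e-9))
})

test_that("phantom generation is bit-identical for a fixed seed", {
  small <- function(seed) digital_femur_spec(
    extent_mm = c(70, 60, 60), shaft_length_mm = 25, neck_length_mm = 25,
    head_radius_mm = 12, troch_radius_mm = 6,
    rods = rod_layout(x = c(15, 40), y = c(8, 8), radius_mm = 5,
                      densities = c(0, 200), z_range_mm = c(3, 55)),
    noise_sd_hu = 10, seed = seed)
  a <- generate_phantom(small(77))
  b <- generate_phantom(small(77))
  expect_identical(a$hu$values, b$hu$values)
  expect_identical(a$mask$mask, b$mask$mask)
  c2 <- generate_phantom(small(78))
  expect_false(identical(a$hu$values, c2$hu$values))
})

test_that("oracle centre-line aBMD follows the rho*d/1000 closed form", {
  # near-homogeneous bone: shell and core densities almost equal
  spec <- digital_femur_spec(cortical_density = 800,
                             trabecular_density = 800 - 1e-9)
  geom <- ctxa:::femur_geometry(spec)
  # thin strip through the shaft axis, away from trochanter and caps
  orc <- oracle_projection(spec, roi = list(x = geom$shaft_c[1] + c(-0.05, 0.05),
                                            z = c(45, 60)))
  d_cm <- 2 * spec$shaft_radius_mm / 10
  expect_equal(orc$abmd_gcm2, 800 * d_cm / 1000, tolerance = 0.01)
})

test_that("oracle cortical fraction matches the analytic shell-core ratio", {
  spec <- default_spec()
  geom <- ctxa:::femur_geometry(spec)
  orc <- oracle_projection(spec, roi = list(x = geom$shaft_c[1] + c(-20, 20),
                                            z = c(45, 60)))
  R <- spec$shaft_radius_mm; r <- R - spec$cortical_thickness_mm
  vs <- R^2 - r^2; vc <- r^2                      # per unit length
  frac <- spec$cortical_density * vs /
    (spec$cortical_density * vs + spec$trabecular_density * vc)
  expect_equal(orc$cortical_fraction, frac, tolerance = 0.005)
})

test_that("oracle converges: 10x and 20x resolutions agree within 0.5%", {
  spec <- default_spec()
  roi <- list(x = c(20, 80), z = c(40, 110))
  o10 <- oracle_projection(spec, roi, factor = 10)
  o20 <- oracle_projection(spec, roi, factor = 20)
  expect_lt(abs(o10$mass_g / o20$mass_g - 1), 0.005)
  expect_lt(abs(o10$area_cm2 / o20$area_cm2 - 1), 0.005)
  expect_lt(abs(o10$cortical_fraction - o20$cortical_fraction), 0.005)
})

test_that("full pipeline on a zero-noise phantom recovers the calibration", {
  pl <- pipeline_fixture()
  spec <- pl$ph$spec
  expect_lt(abs(pl$fit$slope / spec$slope - 1), 0.01)
  # intercept on the density scale: compare predicted density of water HU
  hu_w <- -spec$intercept / spec$slope
  expect_lt(abs(pl$fit$slope * hu_w + pl$fit$intercept), 2)  # mg/cm3
  # total bone mass within 5% of the analytic truth
  orc <- oracle_projection(spec)
  expect_lt(abs(oriented_mass_g(pl$ov) / orc$mass_g - 1), 0.05)
})

test_that("longitudinal cohort generator honours its parameters", {
  z <- generate_longitudinal_cohort(10, 3, within_sd = 0, seed = 4)
  expect_equal(rms_precision(z)$rms_sd, 0, tolerance = 1e-12)
  a <- generate_longitudinal_cohort(22, 3, seed = 12)
  b <- generate_longitudinal_cohort(22, 3, seed = 12)
  expect_identical(a, b)
  expect_equal(nrow(a), 66)
  expect_equal(unname(table(a$patient_id)[1]), 3L)
  dr <- generate_longitudinal_cohort(500, 2, within_sd = 0, drift = 0.01,
                                     seed = 5)
  dd <- with(dr, tapply(bmd, visit, mean))
  expect_equal(unname(dd[2] - dd[1]), 0.01, tolerance = 1e-9)
})

test_that("stable cohorts rarely show significant visit differences", {
  rej <- vapply(1:200, function(i) {
    ch <- generate_longitudinal_cohort(22, 3, mean = 0.647, between_sd = 0.08,
                                       within_sd = 0.012, drift = 0, seed = i)
    v <- split(ch$bmd, ch$visit)
    t.test(v[[1]], v[[2]], paired = TRUE)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(!rej), 0.90)
  expect_lte(mean(!rej), 0.99)
})
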