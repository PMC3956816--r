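test_that("two-point and identity calibrations are recovered exactly", {
  lay <- rod_layout(x = c(10, 30), y = c(20, 20), radius_mm = 5,
                    densities = c(0, 200), z_range_mm = c(0, 8))
  vol <- rod_test_volume(c(0, 100), lay)
  fit <- fit_calibration(vol, lay)
  expect_equal(fit$slope, 2.0, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.0, tolerance = 1e-10)
  expect_equal(fit$beam_hardening_factor, 1.0)
  expect_length(fit$residuals, 2)

  lay3 <- three_rod_layout()
  voli <- rod_test_volume(c(0, 100, 200), lay3)   # HU == nominal density
  fiti <- fit_calibration(voli, lay3)
  expect_equal(fiti$slope, 1.0, tolerance = 1e-12)
  expect_equal(fiti$intercept, 0.0, tolerance = 1e-10)
})

test_that("three noisy rods match the hand-coded least-squares oracle", {
  lay <- three_rod_layout()
  hu <- c(3.7, 81.2, 164.9)                       # additive 'noise'
  vol <- rod_test_volume(hu, lay)
  fit <- fit_calibration(vol, lay)
  orc <- ols_oracle(hu, lay$rods$density)
  expect_equal(fit$slope, orc$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, orc$intercept, tolerance = 1e-10)
})

test_that("degenerate and out-of-grid layouts raise errors", {
  lay1 <- rod_layout(x = c(10, 30), y = c(20, 20), radius_mm = 5,
                     densities = c(100, 100), z_range_mm = c(0, 8))
  vol <- rod_test_volume(c(50, 50), lay1)
  expect_error(fit_calibration(vol, lay1), "distinct")
  layout_out <- rod_layout(x = c(10, 300), y = c(20, 20), radius_mm = 5,
                           densities = c(0, 200), z_range_mm = c(0, 8))
  expect_error(fit_calibration(vol, layout_out), "geometry")
})

test_that("apply_calibration is the stated affine map", {
  v0 <- ct_volume(array(0, c(3, 3, 3)), c(1, 1, 1))
  fit <- structure(list(slope = 2, intercept = 0, residuals = numeric(2),
                        beam_hardening_factor = 1),
                   class = "calibration_fit")
  expect_true(all(apply_calibration(v0, fit)$values == 0))
  v1 <- ct_volume(array(100, c(1, 1, 1)), c(1, 1, 1))
  expect_equal(apply_calibration(v1, fit)$values[1], 200)
  fit2 <- fit
  fit2$beam_hardening_factor <- 1.05
  fit2$intercept <- -10
  expect_equal(apply_calibration(v1, fit2)$values[1], 2 * 1.05 * 100 - 10)
  expect_equal(apply_calibration(v1, fit)$spacing, v1$spacing)
})

test_that("calibration is affine-invariant: transformed HU reproduces densities", {
  lay <- three_rod_layout()
  hu <- c(-12, 95, 207)
  for (ab in list(c(2, 30), c(0.5, -40), c(1.3, 5))) {
    vol <- rod_test_volume(ab[1] * hu + ab[2], lay)
    fit <- fit_calibration(vol, lay)
    cal <- apply_calibration(vol, fit)
    # rod centres must read their nominal density after calibration
    ctr <- cal$values[cbind(lay$rods$x + 1, lay$rods$y + 1, 3)]
    pred <- fit$slope * (ab[1] * hu + ab[2]) + fit$intercept
    fitref <- ols_oracle(hu, lay$rods$density)
    orig <- fitref$slope * hu + fitref$intercept
    expect_equal(pred, orig, tolerance = 1e-9)
    expect_equal(ctr, pred, tolerance = 1e-9)
  }
})

test_that("QA check reports deviation, pass flag and suggested factor", {
  lay <- three_rod_layout()
  vol <- rod_test_volume(c(0, 100, 200), lay)
  fit <- fit_calibration(vol, lay)          # identity calibration
  qa <- qa_check(vol, lay, fit)
  expect_equal(qa$percent_deviation, 0, tolerance = 1e-9)
  expect_true(qa$pass)
  expect_equal(qa$suggested_beam_hardening_factor, 1.0, tolerance = 1e-9)

  # a QA scan reading 190 where 200 is nominal: -5%, fail at 2%, factor 200/190
  vol190 <- rod_test_volume(c(0, 100, 190), lay)
  qa2 <- qa_check(vol190, lay, fit)
  expect_equal(qa2$percent_deviation, -5.0, tolerance = 1e-9)
  expect_false(qa2$pass)
  expect_equal(qa2$suggested_beam_hardening_factor, 200 / 190,
               tolerance = 1e-9)
  qa3 <- qa_check(vol190, lay, fit, tolerance_pct = 6)
  expect_true(qa3$pass)
})

test_that("QA deviation is zero when the QA rod comes from the fitted scanner", {
  lay <- three_rod_layout()
  for (sl in c(0.8, 1.5)) for (ic in c(-20, 10)) {
    hu <- (lay$rods$density - ic) / sl
    vol <- rod_test_volume(hu, lay)
    fit <- fit_calibration(vol, lay)
    qa <- qa_check(vol, lay, fit)
    expect_equal(qa$percent_deviation, 0, tolerance = 1e-7)
  }
})
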