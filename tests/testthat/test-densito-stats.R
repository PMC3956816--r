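test_that("rms precision matches hand evaluation of the stated formula", {
  # identical visits: zero precision error
  ser0 <- data.frame(patient_id = rep(c("a", "b"), each = 3),
                     bmd = rep(c(0.6, 0.7), each = 3))
  p0 <- rms_precision(ser0)
  expect_equal(p0$rms_sd, 0)
  expect_equal(p0$cv_percent, 0)
  # two patients with SDs 0.01 and 0.02 -> sqrt((1e-4 + 4e-4)/2)
  mk <- function(mean, sd) mean + c(-1, 0, 1) * sd  # sd(c(-1,0,1)) = 1
  ser <- data.frame(patient_id = rep(c("a", "b"), each = 3),
                    bmd = c(mk(0.6, 0.01), mk(0.7, 0.02)))
  p <- rms_precision(ser)
  expect_equal(sapply(split(ser$bmd, ser$patient_id), sd),
               c(a = 0.01, b = 0.02), tolerance = 1e-12)
  expect_equal(p$rms_sd, sqrt((0.0001 + 0.0004) / 2), tolerance = 1e-12)
  expect_equal(p$grand_mean, 0.65, tolerance = 1e-12)
  expect_equal(p$cv_percent, 100 * p$rms_sd / 0.65, tolerance = 1e-12)
})

test_that("rms precision is permutation-invariant and scale-equivariant", {
  set.seed(3)
  ser <- generate_longitudinal_cohort(8, 3, seed = 3)
  p <- rms_precision(ser)
  perm <- ser[sample(nrow(ser)), ]
  perm$patient_id <- factor(perm$patient_id,
                            levels = sample(unique(perm$patient_id)))
  expect_equal(rms_precision(perm)$rms_sd, p$rms_sd, tolerance = 1e-12)
  sc <- ser; sc$bmd <- 3.7 * sc$bmd
  psc <- rms_precision(sc)
  expect_equal(psc$rms_sd, 3.7 * p$rms_sd, tolerance = 1e-12)
  expect_equal(psc$cv_percent, p$cv_percent, tolerance = 1e-10)
})

test_that("patients with fewer than two visits are excluded with a warning", {
  ser <- data.frame(patient_id = c("a", "a", "a", "b"),
                    bmd = c(0.6, 0.61, 0.59, 0.7))
  expect_warning(expect_error(rms_precision(ser), ">= 2 patients"))
  ser2 <- rbind(ser, data.frame(patient_id = c("c", "c"), bmd = c(0.5, 0.52)))
  expect_warning(p <- rms_precision(ser2), "excluded")
  expect_equal(p$n_patients, 2)
  expect_error(suppressWarnings(rms_precision(ser2, on_short = "error")))
  # df-weighted variant differs when visit counts differ
  ser3 <- data.frame(patient_id = rep(c("a", "b"), c(3, 4)),
                     bmd = c(0.6, 0.62, 0.58, 0.7, 0.73, 0.67, 0.7))
  sds <- sapply(split(ser3$bmd, ser3$patient_id), sd)
  expect_equal(rms_precision(ser3, weighted = TRUE)$rms_sd,
               sqrt((2 * sds[["a"]]^2 + 3 * sds[["b"]]^2) / 5),
               tolerance = 1e-12)
})

test_that("interobserver comparison reports difference, percent and p", {
  x <- c(0.6, 0.65, 0.7, 0.72)
  same <- interobserver_compare(x, x)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$percent_difference, 0)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  set.seed(5)
  o1 <- rnorm(28, 0.668, 0.14)
  o2 <- o1 + rnorm(28, 0.007, 0.004)
  r <- interobserver_compare(o1, o2)
  expect_equal(r$mean_difference, mean(o2) - mean(o1), tolerance = 1e-12)
  expect_equal(r$percent_difference, 100 * abs(r$mean_difference) / mean(o1),
               tolerance = 1e-12)
  expect_equal(r$p_value, t.test(o2, o1, paired = TRUE)$p.value,
               tolerance = 1e-12)
  expect_error(interobserver_compare(o1, o2[-1]), "pairing")
})

test_that("paired shift is recovered unbiasedly across replicates", {
  delta <- 0.007
  diffs <- vapply(1:1000, function(i) {
    set.seed(i)
    o1 <- rnorm(28, 0.67, 0.14)
    o2 <- o1 + rnorm(28, delta, 0.004)
    interobserver_compare(o1, o2)$mean_difference
  }, numeric(1))
  se <- 0.004 / sqrt(28) / sqrt(1000)
  expect_lt(abs(mean(diffs) - delta), 2 * se)
})

test_that("regression with SEE matches the normal-equation oracle", {
  x <- c(0.5, 0.6, 0.7, 0.8)
  expect_error(regress_with_see(rep(1, 4), x), "degenerate")
  r0 <- regress_with_see(x, x)
  expect_equal(r0$slope, 1, tolerance = 1e-12)
  expect_equal(r0$intercept, 0, tolerance = 1e-12)
  expect_equal(r0$pearson_r, 1, tolerance = 1e-12)
  expect_equal(r0$see, 0, tolerance = 1e-10)
  y <- c(0.41, 0.63, 0.58, 0.93)
  r <- regress_with_see(x, y)
  orc <- ols_oracle(x, y)
  expect_equal(r$slope, orc$slope, tolerance = 1e-12)
  expect_equal(r$intercept, orc$intercept, tolerance = 1e-12)
  expect_equal(r$pearson_r, orc$r, tolerance = 1e-12)
  expect_equal(r$see, orc$see, tolerance = 1e-12)
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(20, 0.7, 0.15); y <- x + rnorm(20, -0.1, 0.05)
    r <- regress_with_see(x, y); orc <- ols_oracle(x, y)
    expect_equal(r$slope, orc$slope, tolerance = 1e-10)
    expect_equal(r$see, orc$see, tolerance = 1e-10)
  }
})

test_that("Welch test matches the formula oracle and is calibrated", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5, 6)
  w <- welch_t(a, b)
  orc <- welch_oracle(a, b)
  expect_equal(w$t, orc$t, tolerance = 1e-10)
  expect_equal(w$df, orc$df, tolerance = 1e-10)
  expect_equal(w$p_value, orc$p, tolerance = 1e-10)
  expect_error(welch_t(c(1, 1), c(2, 2)), "degenerate")
})

test_that("Anderson-Darling case-3 test behaves as expected", {
  set.seed(20)
  x <- rnorm(5000)
  ad <- anderson_darling_normality(x)
  expect_false(ad$reject)
  expect_equal(ad$A2_adjusted, ad$A2 * (1 + 0.75 / 5000 + 2.25 / 5000^2),
               tolerance = 1e-12)
  # affine invariance
  ad2 <- anderson_darling_normality(3 * x + 7)
  expect_equal(ad2$A2, ad$A2, tolerance = 1e-9)
  # power against an exponential alternative
  rej <- vapply(1:200, function(i) {
    set.seed(i); anderson_darling_normality(rexp(200))$reject
  }, logical(1))
  expect_gt(mean(rej), 0.99)
  expect_error(anderson_darling_normality(rep(1, 20)), "degenerate")
  expect_error(anderson_darling_normality(rnorm(5)), "n >= 8")
})

test_that("Anderson-Darling rejection rate is calibrated at the 5% level", {
  rej <- vapply(1:1000, function(i) {
    set.seed(i); anderson_darling_normality(rnorm(5000))$reject
  }, logical(1))
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("t-score helper and summary arithmetic behave", {
  expect_equal(t_score(0.55, 0.85, 0.12), (0.55 - 0.85) / 0.12)
  expect_equal(cv_from_summary(0.7, 0.014), 2.0)
  io <- interobserver_from_means(0.668, 0.675)
  expect_equal(io$mean_difference, 0.007)
  expect_equal(io$percent_difference, 100 * 0.007 / 0.668)
})

test_that("CSV readers validate their schemas", {
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(patient_id = "a", visit = 1, bmd = 0.6), tmp,
            row.names = FALSE)
  expect_s3_class(read_longitudinal_csv(tmp), "data.frame")
  write.csv(data.frame(foo = 1), tmp, row.names = FALSE)
  expect_error(read_longitudinal_csv(tmp), "patient_id")
  expect_error(read_paired_csv(tmp), "study_id")
  expect_error(read_crossdevice_csv(tmp), "subject_id")
  # cross-calibration report with two sites includes a pooling Welch p
  set.seed(30)
  df <- data.frame(subject_id = 1:40,
                   ctxa = rnorm(40, 0.7, 0.15),
                   site = rep(c("s1", "s2"), each = 20))
  df$dxa <- df$ctxa + rnorm(40, 0.1, 0.04)
  write.csv(df, tmp, row.names = FALSE)
  rep <- crosscal_report_from_csv(tmp)
  expect_s3_class(rep$pooled, "regression_result")
  expect_true(rep$pooling_p_value > 0 && rep$pooling_p_value <= 1)
  expect_equal(rep$pooled$n, 40)
})
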