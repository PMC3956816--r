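#' Long-term RMS-SD precision
#'
#' Computes each patient's sample standard deviation over their visits
#' (n-1 denominator, without regard for the rate of bone change) and
#' returns the root-mean-square average of those standard deviations,
#' unweighted across patients. The coefficient of variation uses the grand
#' mean of the patient means. Patients contribute 3 or 4 visits in the
#' intended design; any patient with fewer than 2 visits is excluded with
#' a warning (or an error if `on_short = "error"`).
#'
#' @param series data frame with columns `patient_id` and `bmd`
#'   (g/cm^2); a `visit` column is allowed and ignored by the estimator.
#' @param weighted if TRUE, weight each patient's variance by its degrees
#'   of freedom (`n_i - 1`) instead of the default unweighted average.
#' @param on_short `"warn"` (default, exclude) or `"error"`.
#' @return An object of class `precision_result`: `rms_sd`, `grand_mean`,
#'   `cv_percent`, `n_patients`, `per_patient` (data frame).
#' @export
rms_precision <- function(series, weighted = FALSE, on_short = c("warn", "error")) {
  on_short <- match.arg(on_short)
  stopifnot(is.data.frame(series), all(c("patient_id", "bmd") %in% names(series)))
  sp <- split(series$bmd, series$patient_id)
  nv <- vapply(sp, length, integer(1))
  if (any(nv < 2)) {
    msg <- paste0("patients with <2 visits: ",
                  paste(names(sp)[nv < 2], collapse = ", "))
    if (on_short == "error") stop("rms_precision: ", msg)
    warning("rms_precision: excluded ", msg)
    sp <- sp[nv >= 2]
  }
  if (length(sp) < 2) stop("rms_precision: need >= 2 patients with >= 2 visits")
  sds <- vapply(sp, stats::sd, numeric(1))
  means <- vapply(sp, mean, numeric(1))
  df <- vapply(sp, length, integer(1)) - 1L
  rms <- if (weighted) sqrt(sum(df * sds^2) / sum(df)) else sqrt(mean(sds^2))
  gm <- mean(means)
  structure(list(rms_sd = rms, grand_mean = gm,
                 cv_percent = 100 * rms / gm,
                 n_patients = length(sp),
                 per_patient = data.frame(patient_id = names(sp),
                                          n = df + 1L, mean = means, sd = sds,
                                          row.names = NULL)),
            class = "precision_result")
}

#' @export
print.precision_result <- function(x, ...) {
  cat(sprintf("<precision_result> RMS-SD %.4f g/cm2, grand mean %.3f g/cm2, CV %.1f%% (%d patients)\n",
              x$rms_sd, x$grand_mean, x$cv_percent, x$n_patients))
  invisible(x)
}

#' Interobserver comparison of paired BMD measurements
#'
#' The same studies analyzed independently by two operators: reports the
#' per-observer means, the mean difference (observer 2 minus observer 1),
#' the percent difference relative to observer 1, and a two-tailed t-test
#' p-value (paired by default, since both observers analyze the same
#' scans; set `paired = FALSE` for a Welch test).
#'
#' @param obs1,obs2 numeric vectors of BMD (g/cm^2), equal length >= 3.
#' @param paired use a paired t-test (default) or Welch two-sample.
#' @return A list: `mean_obs1`, `mean_obs2`, `mean_difference`,
#'   `percent_difference`, `p_value`, `degenerate` (TRUE when all paired
#'   differences are identical so the test variance is undefined).
#' @export
interobserver_compare <- function(obs1, obs2, paired = TRUE) {
  if (length(obs1) != length(obs2))
    stop("pairing error: observer series have different lengths")
  if (length(obs1) < 3) stop("interobserver_compare: need >= 3 pairs")
  d <- mean(obs2) - mean(obs1)
  pct <- 100 * abs(d) / mean(obs1)
  degenerate <- paired && stats::sd(obs2 - obs1) == 0
  p <- if (degenerate) {
    if (d == 0) 1 else 0
  } else if (paired) {
    stats::t.test(obs2, obs1, paired = TRUE)$p.value
  } else {
    stats::t.test(obs2, obs1, var.equal = FALSE)$p.value
  }
  list(mean_obs1 = mean(obs1), mean_obs2 = mean(obs2),
       mean_difference = d, percent_difference = pct,
       p_value = p, degenerate = degenerate)
}

#' Cross-device regression with standard error of the estimate
#'
#' Ordinary least squares of `y` on `x` (by convention y = DXA, x = CTXA,
#' matching the slope/intercept orientation of cross-calibration tables),
#' with Pearson correlation and SEE = sqrt(RSS / (n - 2)).
#'
#' @param x,y numeric vectors, n >= 3.
#' @return An object of class `regression_result`: `slope`, `intercept`,
#'   `pearson_r`, `see`, `n`.
#' @export
regress_with_see <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("regress_with_see: need n >= 3")
  if (stats::sd(x) == 0) stop("degenerate error: zero variance in x")
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = stats::cor(x, y),
                 see = sqrt(rss / (n - 2)),
                 n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> slope %.3f, intercept %.3f g/cm2, R %.3f, SEE %.3f g/cm2 (n = %d)\n",
              x$slope, x$intercept, x$pearson_r, x$see, x$n))
  invisible(x)
}

#' Welch two-sample t-test (unequal variances)
#'
#' @param groupA,groupB numeric vectors, each with >= 2 values.
#' @return A list: `t`, `df` (Satterthwaite), `p_value` (two-tailed).
#' @export
welch_t <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0)
    stop("degenerate error: zero variance in both groups")
  tt <- stats::t.test(groupA, groupB, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Anderson-Darling normality test (estimated mean and variance)
#'
#' Case-3 A-squared statistic with the standard small-sample adjustment
#' `A*^2 = A^2 (1 + 0.75/n + 2.25/n^2)` and the 5% critical value 0.752.
#'
#' @param x numeric vector, n >= 8.
#' @return A list: `A2`, `A2_adjusted`, `reject` (at 5%), `p_value`, `n`.
#' @export
anderson_darling_normality <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("anderson_darling_normality: need n >= 8")
  if (stats::sd(x) == 0) stop("degenerate error: constant input")
  at <- nortest::ad.test(x)
  A2 <- unname(at$statistic)
  A2s <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  list(A2 = A2, A2_adjusted = A2s, reject = A2s > 0.752,
       p_value = at$p.value, n = n)
}

#' T-score from a young-normal reference
#'
#' Generic helper `(bmd - young_mean) / young_sd`; no reference population
#' data ship with the package.
#'
#' @param bmd measured BMD g/cm^2.
#' @param young_mean,young_sd young-normal reference mean and SD, g/cm^2.
#' @export
t_score <- function(bmd, young_mean, young_sd) {
  stopifnot(young_sd > 0)
  (bmd - young_mean) / young_sd
}

#' Coefficient of variation from summary values
#'
#' `100 * precision / mean`, the arithmetic linking the mean BMD and
#' RMS-SD precision rows of a precision summary table to its CV row.
#'
#' @param mean_bmd mean BMD g/cm^2; @param precision_sd RMS-SD g/cm^2.
#' @export
cv_from_summary <- function(mean_bmd, precision_sd) 100 * precision_sd / mean_bmd

#' Interobserver difference from summary means
#'
#' Mean difference (observer 2 minus observer 1) and percent difference
#' with observer 1 as denominator.
#'
#' @param mean_obs1,mean_obs2 observer means, g/cm^2.
#' @export
interobserver_from_means <- function(mean_obs1, mean_obs2) {
  d <- mean_obs2 - mean_obs1
  list(mean_difference = d, percent_difference = 100 * abs(d) / mean_obs1)
}

# ---- CSV schemas -----------------------------------------------------------

#' Read densitometry statistics input tables
#'
#' CSV schemas: longitudinal (`patient_id, visit, bmd`), paired observer
#' (`study_id, obs1, obs2`), cross-device (`subject_id, ctxa, dxa` with an
#' optional `site`).
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_longitudinal_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("patient_id", "visit", "bmd") %in% names(df)))
    stop("longitudinal CSV must have columns patient_id, visit, bmd")
  df
}

#' @rdname read_longitudinal_csv
#' @export
read_paired_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("study_id", "obs1", "obs2") %in% names(df)))
    stop("paired CSV must have columns study_id, obs1, obs2")
  df
}

#' @rdname read_longitudinal_csv
#' @export
read_crossdevice_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("subject_id", "ctxa", "dxa") %in% names(df)))
    stop("cross-device CSV must have columns subject_id, ctxa, dxa")
  df
}

#' Precision report from a longitudinal CSV
#'
#' @param path longitudinal CSV (`patient_id, visit, bmd`).
#' @param ... passed to [rms_precision()].
#' @export
precision_report_from_csv <- function(path, ...) {
  rms_precision(read_longitudinal_csv(path), ...)
}

#' Cross-calibration report from a cross-device CSV
#'
#' Per-site and pooled OLS of DXA on CTXA with Pearson R and SEE. The
#' pooling of sites can be justified with [welch_t()] on the per-site
#' CTXA-minus-DXA bias distributions; the Welch p-value is included when
#' the table carries a `site` column with exactly two sites.
#'
#' @param path cross-device CSV (`subject_id, ctxa, dxa[, site]`).
#' @return A list of `regression_result`s (`pooled` plus one per site) and
#'   optionally `pooling_p_value`.
#' @export
crosscal_report_from_csv <- function(path) {
  df <- read_crossdevice_csv(path)
  out <- list(pooled = regress_with_see(df$ctxa, df$dxa))
  if ("site" %in% names(df)) {
    for (s in unique(df$site)) {
      d <- df[df$site == s, ]
      out[[paste0("site_", s)]] <- regress_with_see(d$ctxa, d$dxa)
    }
    if (length(unique(df$site)) == 2) {
      bias <- split(df$ctxa - df$dxa, df$site)
      out$pooling_p_value <- welch_t(bias[[1]], bias[[2]])$p_value
    }
  }
  out
}
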