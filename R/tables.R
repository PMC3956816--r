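# Bundled clinical summary tables: published summary statistics from a
# clinical validation of projected-QCT hip densitometry (long-term
# precision, interobserver comparison, cross-device regression), shipped
# as plain CSV for the consistency checks in the test suite and the
# acceptance script.

clinical_summary_file <- function(name) {
  p <- system.file("extdata", "clinical_summary", name, package = "ctxa")
  if (p == "") stop("bundled summary table not found: ", name)
  p
}

#' Bundled clinical summary tables
#'
#' Summary rows (means, RMS-SD precision, printed CVs; observer means;
#' per-site regression coefficients) from a published clinical validation
#' study of DXA-equivalent hip densitometry from QCT. Patient-level data
#' are not included; these are the printed summary values used for
#' internal-consistency checks.
#'
#' @return A data frame.
#' @export
load_precision_summary <- function() {
  utils::read.csv(clinical_summary_file("precision_summary.csv"))
}

#' @rdname load_precision_summary
#' @export
load_interobserver_summary <- function() {
  utils::read.csv(clinical_summary_file("interobserver_summary.csv"))
}

#' @rdname load_precision_summary
#' @export
load_crosscal_summary <- function() {
  utils::read.csv(clinical_summary_file("crosscal_summary.csv"))
}

#' Locate optional patient-level supplementary data
#'
#' The headline precision and cross-device regression results of the
#' validation study are recomputable only from its patient-level
#' supplementary data files, which are not redistributed with this
#' package. If the user converts them to the package CSV schemas (see
#' [read_longitudinal_csv()]) and places them under
#' `inst/extdata/supplementary/`, this helper returns their paths.
#'
#' @param name one of `"long_term_precision.csv"`, `"interobserver.csv"`,
#'   `"crosscal_pairs.csv"`.
#' @return The file path, or `NA_character_` if absent.
#' @export
supplementary_data_path <- function(name) {
  p <- system.file("extdata", "supplementary", name, package = "ctxa")
  if (p == "") NA_character_ else p
}
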