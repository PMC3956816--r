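#' Analysis configuration
#'
#' Collects every tunable of the pipeline with the standard clinical
#' defaults: segmentation floor -250 mg/cm^3, neighborhood 5 voxels, seed
#' 120 mg/cm^3, cortical threshold 350 mg/cm^3, QA reference 200.0 mg/cm^3.
#' Coordinates are mm in patient axes; voxel indices are 0-based with
#' half-open intervals in all external interfaces.
#'
#' @param volume_path input NIfTI path (may be NULL when a volume object
#'   is passed to [run_analysis()] directly).
#' @param rods a [rod_layout()].
#' @param output_dir report directory.
#' @param box_mm optional list `lo`, `hi` (mm) restricting segmentation.
#' @param segmentation a [segmentation_params()].
#' @param compartment a [compartment_params()].
#' @param qa_nominal,qa_tolerance_pct QA reference density and tolerance.
#' @param apply_beam_hardening opt in to applying the QA-suggested slope
#'   correction factor before calibrating the analysis volume.
#' @param iso_spacing_mm isotropic resampling pitch for the standard pose.
#' @param roi_overrides list of [auto_place_rois()] overrides
#'   (`neck_angle_deg`, `neck_center_mm`, `boundary_z_mm`,
#'   `neck_halfheight_mm`, `neck_box_width_mm`, `side`).
#' @param seed RNG seed recorded in the report.
#' @param verbose logical.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(volume_path = NULL,
                            rods = default_rod_layout(),
                            output_dir = tempfile("ctxa_report_"),
                            box_mm = NULL,
                            segmentation = segmentation_params(),
                            compartment = compartment_params(),
                            qa_nominal = 200.0,
                            qa_tolerance_pct = 2,
                            apply_beam_hardening = FALSE,
                            iso_spacing_mm = NULL,
                            roi_overrides = list(),
                            seed = 1L,
                            verbose = FALSE) {
  structure(list(volume_path = volume_path, rods = rods,
                 output_dir = output_dir, box_mm = box_mm,
                 segmentation = segmentation, compartment = compartment,
                 qa_nominal = qa_nominal, qa_tolerance_pct = qa_tolerance_pct,
                 apply_beam_hardening = apply_beam_hardening,
                 iso_spacing_mm = iso_spacing_mm,
                 roi_overrides = roi_overrides,
                 seed = as.integer(seed), verbose = verbose),
            class = "analysis_config")
}

# 32-bit polynomial hash of the canonical JSON form of the configuration,
# recorded in reports for auditability
config_hash <- function(config) {
  cfg <- config
  cfg$verbose <- NULL
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  b <- utf8ToInt(as.character(js))
  h <- 5381
  for (x in b) h <- ((h %% 2^24) * 33 + h %/% 2^24 * ((33 * 2^24) %% 2^32) +
                       x) %% 2^32
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

run_stage <- function(stage, hint, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s (hint: %s)", stage, conditionMessage(e), hint),
         call. = FALSE)
  })
}

#' Run the full hip analysis pipeline
#'
#' Calibrate (rod fit + QA), segment, fill the cortical envelope, rotate
#' into the standard pose, project, place ROIs, split compartments, and
#' write the report files: `results.csv` / `results.json` (one row per
#' ROI x compartment with aBMD, vBMD, mass, area, volume), an annotated
#' projection PNG, and a text log capturing every default and override.
#' Deterministic given the configuration and seed.
#'
#' @param config an [analysis_config()].
#' @param volume optional [ct_volume()]; read from `config$volume_path`
#'   when NULL.
#' @param qa_volume optional separate QA scan [ct_volume()]; the analysis
#'   volume itself is used for QA when NULL (its rods are in the field of
#'   view).
#' @return Invisibly, a list: `results` (data frame), `rois`, `qa`,
#'   `fit`, `proj`, `files`.
#' @export
run_analysis <- function(config, volume = NULL, qa_volume = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  logline <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    logline <<- c(logline, msg)
    if (config$verbose) message(msg)
  }
  say("ctxa %s | config hash %s | seed %d",
      as.character(utils::packageVersion("ctxa")), config_hash(config),
      config$seed)
  if (is.null(volume))
    volume <- run_stage("read", "check the NIfTI path in volume_path",
                        read_ct_volume(config$volume_path))
  say("volume: %s voxels @ %s mm", paste(dim(volume), collapse = "x"),
      paste(signif(volume$spacing, 4), collapse = "x"))
  fit <- run_stage("calibrate", "verify rod layout coordinates",
                   fit_calibration(volume, config$rods))
  qa <- run_stage("qa", "QA reference rod must be in the layout",
                  qa_check(if (is.null(qa_volume)) volume else qa_volume,
                           config$rods, fit, nominal = config$qa_nominal,
                           tolerance_pct = config$qa_tolerance_pct,
                           apply_correction = TRUE))
  say("calibration: slope %.4f, intercept %.2f; QA deviation %+.2f%% (%s)",
      fit$slope, fit$intercept, qa$percent_deviation,
      if (qa$pass) "pass" else "FAIL")
  if (config$apply_beam_hardening) {
    fit <- qa$corrected_fit
    say("beam-hardening slope factor %.4f applied",
        fit$beam_hardening_factor)
  }
  cal <- apply_calibration(volume, fit)
  box <- if (is.null(config$box_mm)) NULL else
    voxel_box_mm(config$box_mm$lo, config$box_mm$hi, volume$spacing,
                 dim(volume))
  seg <- run_stage("segment", "adjust segmentation thresholds or the box",
                   segment_bone(cal, box, config$segmentation))
  mask <- run_stage("segment", "segmentation produced no bone",
                    fill_cortical_envelope(seg, box))
  say("segmentation: floor %.0f, neighborhood %d, seed %.0f -> %d voxels (%.1f cm3)",
      config$segmentation$floor_threshold,
      config$segmentation$neighborhood_width,
      config$segmentation$seed_threshold, sum(mask$mask),
      mask_volume_cm3(mask))
  rot <- run_stage("orient", "supply manual angles via roi_overrides",
                   estimate_standard_rotation(mask, cal))
  ov <- run_stage("orient", "reduce grid size or raise max_voxels",
                  apply_rotation(cal, mask, rot,
                                 iso_spacing_mm = config$iso_spacing_mm))
  say("orientation: rotation angle %.2f deg, oriented mass %.2f g",
      rotation_angle_deg(rot$R), oriented_mass_g(ov))
  proj <- run_stage("project", "oriented volume is empty",
                    project_coronal(ov))
  rois <- run_stage("roi", "use roi_overrides for manual placement",
                    do.call(auto_place_rois, c(list(proj),
                                               config$roi_overrides)))
  say("rois: neck angle %.1f deg, centre (%.1f, %.1f) mm, boundary z %.1f mm",
      rois$neck$angle_deg, rois$neck$center_mm[1], rois$neck$center_mm[2],
      rois$boundary_z_mm)
  comp <- run_stage("compartments", "check cortical threshold",
                    split_compartments(ov, rois, config$compartment))
  results <- comp$table
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(
    csv = file.path(config$output_dir, "results.csv"),
    json = file.path(config$output_dir, "results.json"),
    png = file.path(config$output_dir, "projection.png"),
    log = file.path(config$output_dir, "analysis.log"))
  utils::write.csv(results, files$csv, row.names = FALSE)
  report <- list(
    software = list(package = "ctxa",
                    version = as.character(utils::packageVersion("ctxa")),
                    config_hash = config_hash(config)),
    parameters = list(
      floor_threshold = config$segmentation$floor_threshold,
      neighborhood_width = config$segmentation$neighborhood_width,
      seed_threshold = config$segmentation$seed_threshold,
      cortical_threshold = config$compartment$cortical_threshold,
      qa_nominal = config$qa_nominal,
      qa_tolerance_pct = config$qa_tolerance_pct,
      apply_beam_hardening = config$apply_beam_hardening,
      seed = config$seed),
    calibration = list(slope = fit$slope, intercept = fit$intercept,
                       beam_hardening_factor = fit$beam_hardening_factor,
                       residuals = fit$residuals),
    qa = list(measured = qa$measured_reference_density,
              nominal = qa$nominal_reference_density,
              percent_deviation = qa$percent_deviation,
              pass = qa$pass),
    rois = list(neck_center_mm = rois$neck$center_mm,
                neck_angle_deg = rois$neck$angle_deg,
                neck_width_mm = rois$neck$width_mm,
                boundary_z_mm = rois$boundary_z_mm,
                side = rois$side),
    results = results)
  jsonlite::write_json(report, files$json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_projection_png(proj, files$png, rois)
  writeLines(logline, files$log)
  invisible(list(results = results, rois = rois, qa = qa, fit = fit,
                 proj = proj, oriented = ov, mask = mask, files = files))
}
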