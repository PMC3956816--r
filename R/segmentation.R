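#' Segmentation parameters
#'
#' The three parameters of the adaptive bone segmentation: a hard floor
#' below which a voxel can never be bone (default -250 mg/cm^3), the width
#' of the cubic neighborhood used for the adaptive local threshold
#' (default 5 voxels), and the initial seed threshold (default 120 mg/cm^3)
#' above which voxels are tentatively classified as bone.
#'
#' @param floor_threshold mg/cm^3; hard lower bound for bone.
#' @param neighborhood_width odd integer >= 3, voxels.
#' @param seed_threshold mg/cm^3; initial classification threshold.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(floor_threshold = -250,
                                neighborhood_width = 5L,
                                seed_threshold = 120) {
  neighborhood_width <- as.integer(neighborhood_width)
  if (neighborhood_width < 3L || neighborhood_width %% 2L == 0L)
    stop("segmentation_params: neighborhood_width must be odd and >= 3")
  if (floor_threshold > seed_threshold)
    stop("segmentation_params: floor_threshold must be <= seed_threshold")
  structure(list(floor_threshold = floor_threshold,
                 neighborhood_width = neighborhood_width,
                 seed_threshold = seed_threshold),
            class = "segmentation_params")
}

#' Segment bone with the 3-parameter adaptive threshold
#'
#' Voxels above the seed threshold form the initial bone set; the set is
#' then refined iteratively: a voxel stays bone only while its density is
#' at least the local mean density over the cubic neighborhood centred on
#' it (and always strictly above the floor threshold). Because the local
#' mean field does not depend on the labels, the erosion reaches its fixed
#' point in a single sweep; the loop runs until the label set is stable
#' (at most 50 iterations) regardless. The refinement drops soft-tissue
#' and deep partial-volume voxels that exceed the seed value next to much
#' denser bone while keeping the outer rim wherever a voxel is at least as
#' dense as its mixed neighborhood. The output mask is limited to the
#' user box.
#'
#' @param volume a [calibrated_volume()] (mg/cm^3).
#' @param box optional [voxel_box()] restricting the analysis; default is
#'   the whole grid.
#' @param params a [segmentation_params()].
#' @return A [bone_mask()] (pre-envelope-fill; see
#'   [fill_cortical_envelope()]).
#' @export
segment_bone <- function(volume, box = NULL, params = segmentation_params()) {
  stopifnot(inherits(volume, "calibrated_volume"),
            inherits(params, "segmentation_params"))
  dims <- dim(volume$values)
  box <- check_box(box, dims)
  d <- volume$values[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2],
                     box$lo[3]:box$hi[3], drop = FALSE]
  # neighborhood width is stated in pixels (in-plane); on anisotropic
  # grids the per-axis voxel count is scaled so the neighborhood stays
  # quasi-isotropic in mm (never below one slice along z)
  half_mm <- (params$neighborhood_width - 1L) / 2 * volume$spacing[1]
  half <- pmax(1L, as.integer(round(half_mm / volume$spacing)))
  B <- d > params$seed_threshold
  ones <- array(1, dim(d))
  lm <- box_sum3(d, half) / box_sum3(ones, half)
  for (it in seq_len(50)) {
    # 1e-6 mg/cm3 slack so exact ties survive floating-point averaging
    keep <- B & d > params$floor_threshold &
      d >= pmax(params$floor_threshold, lm) - 1e-6
    if (identical(keep, B)) break
    B <- keep
  }
  out <- array(FALSE, dims)
  out[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <- B
  bone_mask(out, volume$spacing)
}

#' Fill the cortical envelope of a bone mask
#'
#' Hole filling per axial slice followed by 3D hole filling, so that the
#' mask contains everything inside the outer cortex (marrow is not
#' separated from bone within the envelope). Only the largest 26-connected
#' component intersecting the user box is retained; ties between
#' equal-sized components are broken by proximity of the component
#' centroid to the box centre.
#'
#' @param mask a [bone_mask()].
#' @param box optional [voxel_box()]; its centre is the tie-break anchor.
#' @return A [bone_mask()] containing the filled envelope. An empty input
#'   is returned unchanged with a warning.
#' @export
fill_cortical_envelope <- function(mask, box = NULL) {
  stopifnot(inherits(mask, "bone_mask"))
  if (!any(mask$mask)) {
    warning("fill_cortical_envelope: empty mask, returned unchanged")
    return(mask)
  }
  dims <- dim(mask$mask)
  box <- check_box(box, dims)
  m <- fill_holes_axial(mask$mask)
  m <- fill_holes3(m)
  labs <- label_components3(m, 26)
  nlab <- max(labs)
  if (nlab > 1L) {
    inbox <- array(FALSE, dims)
    inbox[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <- TRUE
    sizes <- tabulate(labs[labs > 0L], nbins = nlab)
    touch <- vapply(seq_len(nlab), function(l) any(labs == l & inbox),
                    logical(1))
    cand <- which(touch)
    if (length(cand) == 0) cand <- seq_len(nlab)
    best <- cand[sizes[cand] == max(sizes[cand])]
    if (length(best) > 1L) {
      centre <- (box$lo + box$hi) / 2
      d2 <- vapply(best, function(l) {
        w <- which(labs == l, arr.ind = TRUE)
        sum((colMeans(w) - centre)^2)
      }, numeric(1))
      best <- best[which.min(d2)]
    }
    m <- labs == best[1]
  }
  bone_mask(m, mask$spacing)
}

#' Total masked volume in cm^3
#' @param mask a [bone_mask()].
#' @export
mask_volume_cm3 <- function(mask) sum(mask$mask) * voxel_volume_cm3(mask$spacing)
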