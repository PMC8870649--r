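# Image substrate: PET volumes, lesion masks, ROI validation, and
# fixed-bound intensity discretization.

DISTRICTS <- c("liver", "lymph_node", "bone", "parenchymal_other")

#' Construct a PET volume
#'
#' A PET volume is a 3-D grid of standardized uptake values (SUV,
#' dimensionless) with voxel spacing in mm.
#'
#' @param voxels 3-D numeric array of SUV values (finite, non-negative).
#' @param spacing Numeric length-3 voxel size `(dx, dy, dz)` in mm.
#' @param origin Numeric length-3 physical offset in mm.
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stopf("PET volume must be a 3-D array")
  if (!all(is.finite(voxels))) stopf("PET volume contains non-finite SUV values")
  if (any(voxels < 0)) stopf("PET volume contains negative SUV values")
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be three positive values (mm)")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = rep_len(as.double(origin), 3L)),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume> %s voxels, spacing %s mm, SUV range [%.3g, %.3g]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Construct a lesion region of interest
#'
#' A lesion ROI is a binary mask congruent with its PET volume, tagged with
#' lesion/patient identity, anatomical district and timepoint.
#'
#' @param mask 3-D logical (or 0/1) array; must be non-empty.
#' @param lesion_id,patient_id Identifiers (scalars).
#' @param district One of `"liver"`, `"lymph_node"`, `"bone"`,
#'   `"parenchymal_other"`.
#' @param timepoint `"T0"` (baseline) or `"T1"` (follow-up).
#' @return An object of class `lesion_roi`.
#' @export
lesion_roi <- function(mask, lesion_id, patient_id = NA_character_,
                       district = "liver", timepoint = c("T0", "T1")) {
  timepoint <- match.arg(timepoint)
  district <- match.arg(district, DISTRICTS)
  if (length(dim(mask)) != 3L) stopf("lesion mask must be a 3-D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stopf("lesion mask contains NA")
  if (!any(mask)) stopf("empty ROI: lesion mask has no voxels")
  structure(list(mask = mask, lesion_id = as.character(lesion_id),
                 patient_id = as.character(patient_id),
                 district = district, timepoint = timepoint),
            class = "lesion_roi")
}

#' @export
print.lesion_roi <- function(x, ...) {
  cat(sprintf("<lesion_roi> %s (%s, %s): %d voxels\n", x$lesion_id,
              x$district, x$timepoint, sum(x$mask)))
  invisible(x)
}

#' Load a PET volume from a NIfTI file
#'
#' @param path Path to a 3-D NIfTI image of SUV values.
#' @return A [pet_volume()].
#' @export
load_volume <- function(path) {
  img <- read_nifti(path)
  if (length(dim(img$data)) != 3L)
    stopf("expected a 3-D PET image, got %d-D: %s", length(dim(img$data)), path)
  pet_volume(img$data, spacing = img$spacing[1:3], origin = img$origin)
}

#' Load a lesion mask from a NIfTI file
#'
#' Voxels with value > 0.5 are inside the ROI.
#'
#' @param path Path to a 3-D NIfTI mask on the PET grid.
#' @inheritParams lesion_roi
#' @return A [lesion_roi()].
#' @export
load_mask <- function(path, lesion_id, patient_id = NA_character_,
                      district = "liver", timepoint = "T0") {
  img <- read_nifti(path)
  if (length(dim(img$data)) != 3L)
    stopf("expected a 3-D mask, got %d-D: %s", length(dim(img$data)), path)
  lesion_roi(img$data > 0.5, lesion_id, patient_id, district, timepoint)
}

check_congruent <- function(volume, roi) {
  if (!identical(dim(volume$voxels), dim(roi$mask)))
    stopf("mask shape (%s) does not match volume shape (%s)",
          paste(dim(roi$mask), collapse = "x"),
          paste(dim(volume$voxels), collapse = "x"))
}

#' Extract ROI voxel values
#'
#' Returns the SUV values at mask-true voxels in deterministic
#' (column-major, i.e. lexicographic index) order.
#'
#' @param volume A [pet_volume()].
#' @param roi A [lesion_roi()] congruent with `volume`.
#' @return Numeric vector of SUV values.
#' @export
roi_voxels <- function(volume, roi) {
  check_congruent(volume, roi)
  volume$voxels[roi$mask]
}

#' Validate an ROI against the minimum-size inclusion rule
#'
#' Lesions smaller than `min_voxels` voxels are excluded from feature
#' extraction so that texture matrices are well populated; with ~3 mm
#' isotropic PET voxels the default 16-voxel floor corresponds to about
#' 0.443 cm^3.
#'
#' @param roi A [lesion_roi()].
#' @param volume The [pet_volume()] the mask lives on.
#' @param min_voxels Minimum voxel count (default 16).
#' @return A list with `pass` (logical), `n_voxels`, `volume_ml` (physical
#'   ROI volume in mL) and `reason` (string when failing).
#' @export
validate_roi <- function(roi, volume, min_voxels = 16) {
  check_congruent(volume, roi)
  n <- sum(roi$mask)
  vol_ml <- n * prod(volume$spacing) / 1000
  if (n < min_voxels)
    list(pass = FALSE, n_voxels = n, volume_ml = vol_ml,
         reason = sprintf("ROI has %d voxels, fewer than the required %d",
                          n, as.integer(min_voxels)))
  else list(pass = TRUE, n_voxels = n, volume_ml = vol_ml, reason = NA_character_)
}

#' Fixed-bound discretization configuration
#'
#' Absolute intensity rescaling: SUVs in `[lower, upper]` are mapped to
#' `n_bins` levels of equal width. The defaults (0-60 SUV, 64 bins, width
#' 0.9375) are the standard absolute-rescaling setup for somatostatin
#' receptor PET. A custom `bin_width` may be supplied instead (e.g. 0.95),
#' in which case the last bin absorbs the remainder up to `upper`.
#'
#' @param lower,upper SUV bounds of the rescaling window.
#' @param n_bins Number of grey levels.
#' @param bin_width Optional explicit bin width; default `(upper-lower)/n_bins`.
#' @return An object of class `disc_config`.
#' @export
disc_config <- function(lower = 0, upper = 60, n_bins = 64, bin_width = NULL) {
  if (upper <= lower) stopf("upper_bound must exceed lower_bound")
  if (!is_count(n_bins) || n_bins < 2) stopf("n_bins must be an integer >= 2")
  if (is.null(bin_width)) bin_width <- (upper - lower) / n_bins
  if (bin_width <= 0) stopf("bin_width must be positive")
  structure(list(lower = lower, upper = upper, n_bins = as.integer(n_bins),
                 bin_width = bin_width),
            class = "disc_config")
}

# Map SUVs to 0-based grey levels, clamping outside the window.
discretize_levels <- function(values, cfg) {
  lev <- floor((values - cfg$lower) / cfg$bin_width)
  pmin(pmax(lev, 0), cfg$n_bins - 1L)
}

#' Discretize ROI intensities into a fixed-bound histogram
#'
#' Bin index is `floor((v - lower)/bin_width)`; values below `lower` fall in
#' the first bin and values at or above `upper` in the last bin, so the
#' mapping is total on `[0, Inf)`.
#'
#' @param values Numeric vector of SUVs (non-empty, finite).
#' @param cfg A [disc_config()].
#' @return An `intensity_histogram`: list with `counts`, `probabilities`,
#'   `bin_edges`, `bin_centers` and `n`.
#' @export
discretize <- function(values, cfg = disc_config()) {
  if (length(values) == 0) stopf("cannot discretize an empty value set")
  if (!all(is.finite(values))) stopf("non-finite SUV values in discretize()")
  lev <- discretize_levels(values, cfg)
  counts <- tabulate(lev + 1L, nbins = cfg$n_bins)
  edges <- cfg$lower + cfg$bin_width * seq(0L, cfg$n_bins)
  structure(list(counts = counts,
                 probabilities = counts / length(values),
                 bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 n = length(values)),
            class = "intensity_histogram")
}
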