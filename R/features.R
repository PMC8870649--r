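# Radiomics feature families: first-order histogram (HISTO_), conventional
# SUV statistics (SUV_, MTV, TLG), shape, and GLCM texture.
#
# Degenerate statistics (e.g. skewness of a zero-spread histogram) are
# reported as NA, never silently 0; downstream selection drops features
# that are missing in any lesion.

#' First-order histogram features
#'
#' Weighted moments over discretized bin centers `x_i` with probabilities
#' `p_i`: skewness is the third and kurtosis the fourth standardized moment
#' (non-excess, so a Gaussian gives 3). Entropy is in bits
#' (`-sum p log2 p`), energy is `sum p^2`.
#'
#' @param hist An `intensity_histogram` from [discretize()].
#' @return Named numeric vector `Skewness`, `Kurtosis`, `Entropy`, `Energy`;
#'   skewness/kurtosis are `NA` when the histogram has zero spread.
#' @export
histo_features <- function(hist) {
  p <- hist$probabilities
  x <- hist$bin_centers
  mu <- sum(p * x)
  v <- sum(p * (x - mu)^2)
  if (v > 0) {
    s <- sqrt(v)
    skew <- sum(p * (x - mu)^3) / s^3
    kurt <- sum(p * (x - mu)^4) / v^2
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  pp <- p[p > 0]
  c(Skewness = skew, Kurtosis = kurt,
    Entropy = -sum(pp * log2(pp)), Energy = sum(p^2))
}

#' Conventional SUV statistics
#'
#' Order statistics and moments of the raw (undiscretized) SUVs, plus the
#' metabolic tumor volume MTV (mL) and the TLG-style product
#' `SUV_mean * MTV`.
#'
#' @param values Raw SUV values of the ROI (non-empty).
#' @param spacing Voxel size `(dx, dy, dz)` in mm.
#' @return Named vector `SUV_min`, `SUV_mean`, `SUV_max`, `SUV_std`, `MTV`,
#'   `TLG`. `SUV_std` is the population standard deviation.
#' @export
conventional_features <- function(values, spacing) {
  if (length(values) == 0) stopf("conventional_features: empty ROI")
  n <- length(values)
  m <- mean(values)
  mtv <- n * prod(spacing) / 1000
  c(SUV_min = min(values), SUV_mean = m, SUV_max = max(values),
    SUV_std = sqrt(sum((values - m)^2) / n), MTV = mtv, TLG = m * mtv)
}

#' Shape features of a voxelized ROI
#'
#' Volume in mL and sphericity `pi^(1/3) (6V)^(2/3) / A`, where `A` is the
#' surface area of the voxelized boundary obtained by counting exposed
#' voxel faces (anisotropic spacing respected).
#'
#' @param roi A [lesion_roi()].
#' @param spacing Voxel size `(dx, dy, dz)` in mm.
#' @return Named vector `Volume_mL`, `Sphericity`.
#' @export
shape_features <- function(roi, spacing) {
  m <- roi$mask
  d <- dim(m)
  vol_mm3 <- sum(m) * prod(spacing)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  inner <- function(off) {
    sh <- pad[(2:(d[1] + 1)) + off[1], (2:(d[2] + 1)) + off[2],
              (2:(d[3] + 1)) + off[3]]
    sum(m & !sh)
  }
  face_areas <- c(spacing[2] * spacing[3], spacing[2] * spacing[3],
                  spacing[1] * spacing[3], spacing[1] * spacing[3],
                  spacing[1] * spacing[2], spacing[1] * spacing[2])
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  area <- sum(vapply(seq_len(6), function(i) inner(offs[i, ]), 0) * face_areas)
  c(Volume_mL = vol_mm3 / 1000,
    Sphericity = pi^(1 / 3) * (6 * vol_mm3)^(2 / 3) / area)
}

#' GLCM texture configuration
#'
#' @param distance Offset length in voxels (default 1).
#' @param mode `"3D-13dir"` (13 unique 3-D directions) or `"2D-4dir"`
#'   (axial-plane directions only).
#' @return An object of class `glcm_config`. The matrix is always symmetric
#'   and features are averaged over directions.
#' @export
glcm_config <- function(distance = 1, mode = c("3D-13dir", "2D-4dir")) {
  mode <- match.arg(mode)
  if (!is_count(distance) || distance < 1) stopf("distance must be >= 1")
  structure(list(distance = as.integer(distance), mode = mode),
            class = "glcm_config")
}

glcm_directions <- function(mode) {
  if (mode == "2D-4dir")
    rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0))
  else rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# Symmetric co-occurrence counts of grey-level pairs at one voxel offset;
# both members of a pair must lie in the mask.
glcm_one_direction <- function(lev, mask, off) {
  d <- dim(mask)
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  sx <- ix + off[1]; sy <- iy + off[2]; sz <- iz + off[3]
  kx <- sx >= 1 & sx <= d[1]; ky <- sy >= 1 & sy <= d[2]; kz <- sz >= 1 & sz <= d[3]
  if (!any(kx) || !any(ky) || !any(kz)) return(NULL)
  a_mask <- mask[ix[kx], iy[ky], iz[kz], drop = FALSE]
  b_mask <- mask[sx[kx], sy[ky], sz[kz], drop = FALSE]
  keep <- a_mask & b_mask
  if (!any(keep)) return(NULL)
  a <- lev[ix[kx], iy[ky], iz[kz], drop = FALSE][keep]
  b <- lev[sx[kx], sy[ky], sz[kz], drop = FALSE][keep]
  cbind(i = c(a, b), j = c(b, a))   # symmetric
}

glcm_stats <- function(pairs) {
  tab <- table(pairs[, "i"], pairs[, "j"])
  p <- as.vector(tab) / sum(tab)
  i <- as.numeric(rep(as.numeric(rownames(tab)), times = ncol(tab)))
  j <- as.numeric(rep(as.numeric(colnames(tab)), each = nrow(tab)))
  keep <- p > 0
  p <- p[keep]; i <- i[keep]; j <- j[keep]
  mi <- sum(p * i); mj <- sum(p * j)
  si <- sqrt(sum(p * (i - mi)^2)); sj <- sqrt(sum(p * (j - mj)^2))
  corr <- if (si > 0 && sj > 0) sum(p * (i - mi) * (j - mj)) / (si * sj)
          else NA_real_
  c(Energy = sum(p^2),
    Entropy = -sum(p * log2(p)),
    Homogeneity = sum(p / (1 + abs(i - j))),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    Dissimilarity = sum(abs(i - j) * p))
}

#' GLCM texture features
#'
#' Builds a symmetric grey-level co-occurrence matrix per direction at the
#' configured voxel offset (pairs entirely inside the ROI), normalizes each
#' to probabilities, computes `Energy`, `Entropy`, `Homogeneity`,
#' `Contrast`, `Correlation`, `Dissimilarity`, and averages the features
#' over directions with at least one pair.
#'
#' @param volume A [pet_volume()].
#' @param roi A [lesion_roi()] congruent with `volume`.
#' @param hist_cfg A [disc_config()] for grey-level mapping.
#' @param glcm_cfg A [glcm_config()].
#' @return Named numeric vector of the six features; all `NA` when no
#'   direction yields a voxel pair.
#' @export
glcm_features <- function(volume, roi, hist_cfg = disc_config(),
                          glcm_cfg = glcm_config()) {
  check_congruent(volume, roi)
  lev <- array(discretize_levels(volume$voxels, hist_cfg), dim(volume$voxels))
  dirs <- glcm_directions(glcm_cfg$mode) * glcm_cfg$distance
  per_dir <- list()
  for (k in seq_len(nrow(dirs))) {
    pairs <- glcm_one_direction(lev, roi$mask, dirs[k, ])
    if (!is.null(pairs)) per_dir[[length(per_dir) + 1L]] <- glcm_stats(pairs)
  }
  nm <- c("Energy", "Entropy", "Homogeneity", "Contrast", "Correlation",
          "Dissimilarity")
  if (length(per_dir) == 0)
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  rowMeans(do.call(cbind, per_dir), na.rm = FALSE)[nm]
}

#' Extract the full radiomics feature vector for one lesion
#'
#' Composes histogram, conventional, shape and GLCM features into one named
#' vector with family-prefixed names (`HISTO_`, `SUV_`, `SHAPE_`, `GLCM_`).
#' Raw-value (undiscretized) skewness/kurtosis are also emitted under
#' `HISTO_Skewness_raw` / `HISTO_Kurtosis_raw` for diagnostics.
#'
#' @param volume A [pet_volume()].
#' @param roi A [lesion_roi()] that passes [validate_roi()].
#' @param hist_cfg A [disc_config()].
#' @param glcm_cfg A [glcm_config()].
#' @param min_voxels ROI inclusion floor passed to [validate_roi()].
#' @return Named numeric feature vector (attributes: `lesion_id`, `district`).
#' @export
extract_features <- function(volume, roi, hist_cfg = disc_config(),
                             glcm_cfg = glcm_config(), min_voxels = 16) {
  v <- validate_roi(roi, volume, min_voxels)
  if (!v$pass) stopf("ROI %s rejected: %s", roi$lesion_id, v$reason)
  vals <- roi_voxels(volume, roi)
  hist <- discretize(vals, hist_cfg)
  h <- histo_features(hist)
  cv <- conventional_features(vals, volume$spacing)
  sh <- shape_features(roi, volume$spacing)
  gl <- glcm_features(volume, roi, hist_cfg, glcm_cfg)
  n <- length(vals)
  m <- mean(vals); s2 <- sum((vals - m)^2) / n
  raw_skew <- if (s2 > 0) sum((vals - m)^3) / n / s2^1.5 else NA_real_
  raw_kurt <- if (s2 > 0) sum((vals - m)^4) / n / s2^2 else NA_real_
  out <- c(stats::setNames(h, paste0("HISTO_", names(h))),
           HISTO_Skewness_raw = raw_skew, HISTO_Kurtosis_raw = raw_kurt,
           cv[c("SUV_min", "SUV_mean", "SUV_max", "SUV_std", "MTV", "TLG")],
           SHAPE_Volume_mL = unname(sh["Volume_mL"]),
           SHAPE_Sphericity = unname(sh["Sphericity"]),
           stats::setNames(gl, paste0("GLCM_", names(gl))))
  attr(out, "lesion_id") <- roi$lesion_id
  attr(out, "district") <- roi$district
  out
}
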