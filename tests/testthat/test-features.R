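test_that("histogram moments match the per-voxel oracle on random ROIs", {
  set.seed(31)
  for (i in 1:25) {
    vals <- runif(sample(10:300, 1), 0, 65)
    got <- histo_features(discretize(vals))
    want <- oracle_histo(vals)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("histogram moment edge cases behave", {
  # symmetric two-bin histogram: skewness 0, kurtosis 1
  h <- discretize(c(rep(1, 5), rep(10, 5)))
  f <- histo_features(h)
  expect_equal(unname(f["Skewness"]), 0, tolerance = 1e-12)
  expect_equal(unname(f["Kurtosis"]), 1, tolerance = 1e-12)
  expect_equal(unname(f["Entropy"]), 1, tolerance = 1e-12)  # two equal bins
  expect_equal(unname(f["Energy"]), 0.5, tolerance = 1e-12)
  # zero spread: flagged missing, not zero
  fz <- histo_features(discretize(rep(5, 20)))
  expect_true(is.na(fz["Skewness"]) && is.na(fz["Kurtosis"]))
  expect_equal(unname(fz["Energy"]), 1)
  # moment inequality kurtosis >= skewness^2 + 1
  set.seed(32)
  for (i in 1:50) {
    v <- rlnorm(sample(20:200, 1), 1.5, runif(1, 0.2, 1))
    f <- histo_features(discretize(v))
    if (!is.na(f["Kurtosis"]))
      expect_gte(f[["Kurtosis"]], f[["Skewness"]]^2 + 1 - 1e-9)
  }
})

test_that("Gaussian intensities give skewness ~0 and kurtosis ~3", {
  set.seed(33)
  v <- rnorm(1e5, 30, 4)   # well inside [0, 60]
  f <- histo_features(discretize(v))
  expect_lt(abs(f[["Skewness"]]), 0.05)
  expect_lt(abs(f[["Kurtosis"]] - 3), 0.1)
})

test_that("conventional features: order statistics, MTV, TLG", {
  f <- conventional_features(c(1, 5, 3), c(3, 3, 3))
  expect_equal(unname(f[c("SUV_min", "SUV_mean", "SUV_max")]), c(1, 3, 5))
  f16 <- conventional_features(rep(2, 16), rep(27.69^(1 / 3), 3))
  expect_equal(unname(f16["MTV"]), 0.443, tolerance = 1e-3)
  expect_equal(unname(f16["SUV_std"]), 0)
  expect_equal(unname(f16["TLG"]), unname(2 * f16["MTV"]))
  expect_error(conventional_features(numeric(0), c(3, 3, 3)), "empty")
})

test_that("shape features: cube closed form, consistency, refinement", {
  v1 <- lesion_roi(array(TRUE, c(1, 1, 1)), "a")
  s <- shape_features(v1, c(1, 1, 1))
  expect_equal(unname(s["Volume_mL"]), 0.001)
  expect_equal(unname(s["Sphericity"]), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
  # volume equals MTV on the same ROI
  fx <- random_volume_roi(seed = 34, spacing = c(2, 2.5, 3))
  mtv <- conventional_features(roi_voxels(fx$volume, fx$roi),
                               fx$volume$spacing)[["MTV"]]
  expect_equal(shape_features(fx$roi, fx$volume$spacing)[["Volume_mL"]], mtv)
  # a refined digital ball is more spherical than a coarse one (the
  # face-counted staircase limit is ~2/3, not 1)
  s2 <- shape_features(ball_roi(2), c(1, 1, 1))[["Sphericity"]]
  s4 <- shape_features(ball_roi(4), c(1, 1, 1))[["Sphericity"]]
  expect_gt(s4, s2)
  expect_lt(s4, 1)
})

test_that("GLCM: constant ROI collapses to a single cell", {
  v <- pet_volume(array(10, c(4, 4, 4)))
  r <- lesion_roi(array(TRUE, c(4, 4, 4)), "c")
  g <- glcm_features(v, r)
  expect_equal(unname(g["Energy"]), 1)
  expect_equal(unname(g["Entropy"]), 0)
  expect_equal(unname(g["Contrast"]), 0)
  expect_equal(unname(g["Homogeneity"]), 1)
  expect_true(is.na(g["Correlation"]))  # zero marginal variance
})

test_that("GLCM on an alternating 1-D stripe matches hand enumeration", {
  cfg <- disc_config(lower = 0, upper = 16, n_bins = 16)  # width 1, level = floor(SUV)
  n <- 9
  vox <- array(rep(c(2.5, 7.5), length.out = n), c(1, 1, n))
  v <- pet_volume(vox)
  r <- lesion_roi(array(TRUE, c(1, 1, n)), "s")
  g <- glcm_features(v, r, hist_cfg = cfg)   # only the z direction has pairs
  expect_equal(unname(g["Energy"]), 0.5)
  expect_equal(unname(g["Contrast"]), (7 - 2)^2)
  expect_equal(unname(g["Dissimilarity"]), 5)
  expect_equal(unname(g["Homogeneity"]), 1 / 6)
  expect_equal(unname(g["Correlation"]), -1)
  expect_equal(unname(g["Entropy"]), 1)
})

test_that("GLCM features are invariant to an in-bin affine shift", {
  fx <- random_volume_roi(seed = 35)
  cfg <- disc_config()
  g1 <- glcm_features(fx$volume, fx$roi, cfg)
  # shift every SUV to its bin center: same levels, same GLCM
  lev <- floor(fx$volume$voxels / cfg$bin_width)
  centered <- pet_volume(array((lev + 0.5) * cfg$bin_width, dim(lev)),
                         fx$volume$spacing)
  expect_equal(glcm_features(centered, fx$roi, cfg), g1, tolerance = 1e-12)
})

test_that("extract_features composes families and flags degeneracy", {
  les <- synth_lesion_volume(lesion_spec(n_voxels = 600, mean_suv = 12,
                                         skewness = 1.5, seed = 36))
  fv <- extract_features(les$volume, les$roi)
  expect_true(all(c("HISTO_Skewness", "SUV_max", "MTV", "SHAPE_Sphericity",
                    "GLCM_Entropy") %in% names(fv)))
  expect_gt(fv[["HISTO_Skewness"]], 0)  # right-skewed generator
  expect_identical(extract_features(les$volume, les$roi), fv)  # deterministic
  # constant lesion: conventional present, HISTO/GLCM spread stats missing
  d <- c(4, 2, 2)
  vc <- pet_volume(array(3, d), spacing = c(3, 3, 3))
  rc <- lesion_roi(array(TRUE, d), "const")
  fc <- extract_features(vc, rc)
  expect_true(is.na(fc["HISTO_Skewness"]))
  expect_identical(unname(fc["SUV_mean"]), 3)
  # sub-minimal ROI rejected with reason
  m <- array(FALSE, d); m[1:8] <- TRUE
  expect_error(extract_features(vc, lesion_roi(m, "small")), "fewer")
})
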