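# Shared fixtures and independent oracles, built in code at test time.

# Random volume + mask pair on a common grid.
random_volume_roi <- function(dims = c(6, 7, 5), p_mask = 0.4, seed = 1,
                              spacing = c(3, 3, 3)) {
  set.seed(seed)
  vox <- array(runif(prod(dims), 0, 40), dims)
  mask <- array(runif(prod(dims)) < p_mask, dims)
  if (!any(mask)) mask[1] <- TRUE
  list(volume = pet_volume(vox, spacing = spacing),
       roi = lesion_roi(mask, lesion_id = "rtest"))
}

# Digital ball ROI of radius r (isotropic unit spacing).
ball_roi <- function(r) {
  d <- 2 * r + 3
  g <- seq_len(d) - (d + 1) / 2
  rad <- outer(outer(g^2, g^2, "+"), g^2, "+")
  lesion_roi(array(rad <= r^2, c(d, d, d)), lesion_id = "ball")
}

# Independent oracle for histogram moments: per-voxel computation over the
# discretized values (vs the package's per-bin weighted sums).
oracle_histo <- function(values, cfg = disc_config()) {
  lev <- pmin(pmax(floor((values - cfg$lower) / cfg$bin_width), 0),
              cfg$n_bins - 1)
  centers <- cfg$lower + cfg$bin_width * (lev + 0.5)
  m <- mean(centers)
  s2 <- mean((centers - m)^2)
  counts <- table(lev)
  p <- as.numeric(counts) / length(values)
  c(Skewness = if (s2 > 0) mean((centers - m)^3) / s2^1.5 else NA_real_,
    Kurtosis = if (s2 > 0) mean((centers - m)^4) / s2^2 else NA_real_,
    Entropy = -sum(p * log2(p)),
    Energy = sum(p^2))
}

# Pair-counting AUC oracle: P(score_pos > score_neg) + 0.5 P(tie).
oracle_auc <- function(scores, labels, positive = 0) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive-scan Youden oracle (predict positive when score >= t).
oracle_youden <- function(scores, labels, positive = 0) {
  pos <- labels == positive
  thr <- c(sort(unique(scores)), Inf)
  j <- vapply(thr, function(t)
    mean(scores[pos] >= t) + mean(scores[!pos] < t) - 1, 0)
  best <- which(j == max(j))
  best <- best[which.min(thr[best])]
  list(cutoff = thr[best], j = j[best])
}

# Feature table with two informative features (shift d) and noise columns.
sim_selection_table <- function(n = 300, d = 1, n_noise = 50, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * (n_noise + 2)), n)
  colnames(x) <- c("inf_1", "inf_2", sprintf("noise_%02d", seq_len(n_noise)))
  x[, 1] <- x[, 1] + d * y
  x[, 2] <- x[, 2] + d * y
  list(table = as.data.frame(x), labels = y)
}
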