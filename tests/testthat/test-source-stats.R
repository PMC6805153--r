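grid444 <- source_grid(c(4, 4, 4), 5)

test_that("neighbor control maps average voxelwise", {
  m1 <- activation_map(rep(0, 64), grid444, freq = 0.71)
  m2 <- activation_map(rep(2, 64), grid444, freq = 0.89)
  ctl <- neighbor_control_map(m1, m2)
  expect_equal(ctl$values, rep(1, 64))
  expect_equal(neighbor_control_map(m1, m1)$values, m1$values)

  # averaging two independent-noise maps halves the variance
  set.seed(51)
  v1 <- matrix(rexp(64 * 400), 64)
  v2 <- matrix(rexp(64 * 400), 64)
  ctl_var <- var(as.vector((v1 + v2) / 2))
  expect_equal(ctl_var, var(as.vector(v1)) / 2, tolerance = 0.05)

  g2 <- source_grid(c(2, 2, 2), 5)
  expect_error(neighbor_control_map(m1, activation_map(rep(1, 8), g2)),
               "grid mismatch")
})

test_that("grid smoothing conserves mass, fixes uniform maps, and logs with a floor", {
  u <- activation_map(rep(3, 64), grid444)
  sm <- smooth_and_log(u, fwhm = 10, log = FALSE)
  expect_equal(sm$values, rep(3, 64), tolerance = 1e-12)   # uniform invariant
  expect_equal(smooth_and_log(u, fwhm = 10)$values, rep(log(3), 64),
               tolerance = 1e-12)

  # fwhm = 0 is the identity (before log)
  set.seed(52)
  v <- rexp(64)
  expect_equal(smooth_and_log(activation_map(v, grid444), fwhm = 0,
                              log = FALSE)$values, v)

  # delta at a deep interior voxel, fwhm = 2 x spacing: kernel
  # row-normalization keeps the delta's mass within 1% (normalization
  # deviates only near grid borders)
  g6 <- source_grid(c(8, 8, 8), 5)
  interior <- which.min(rowSums(g6$positions^2))
  delta <- numeric(512); delta[interior] <- 1
  smd <- smooth_and_log(activation_map(delta, g6), fwhm = 10,
                        log = FALSE)$values
  expect_equal(sum(smd), 1, tolerance = 0.01)
  expect_gt(smd[interior], max(smd[-interior]))   # mode stays at the delta

  expect_warning(smooth_and_log(activation_map(rep(0, 64), grid444), fwhm = 0),
                 "all-zero")
})

test_that("cluster test finds injected effects and nothing under the null", {
  set.seed(53)
  ns <- 12
  base <- matrix(rnorm(ns * 64), ns)
  # identical target/control: zero clusters
  r0 <- voxelwise_cluster_test(base, base, grid444, n_perm = 256)
  expect_length(r0$clusters, 0)

  # an injected 2x2x2 corner region with a strong paired effect
  region <- which(apply(grid444$positions, 1, function(p) all(p <= -2)))
  target <- base
  target[, region] <- target[, region] + 2
  r1 <- voxelwise_cluster_test(target, base, grid444, n_perm = 256, seed = 1)
  expect_gte(length(r1$clusters), 1)
  expect_true(r1$clusters[[1]]$peak %in% region)
  expect_lt(r1$clusters[[1]]$p_fwe, 0.01)
  expect_true(all(r1$voxel_t[r1$clusters[[1]]$voxels] > r1$t_threshold))

  # clusters are disjoint and peak t is the member maximum
  if (length(r1$clusters) > 1) {
    vox <- unlist(lapply(r1$clusters, `[[`, "voxels"))
    expect_equal(length(vox), length(unique(vox)))
  }
  expect_equal(r1$clusters[[1]]$peak_t,
               max(r1$voxel_t[r1$clusters[[1]]$voxels]))
})

test_that("cluster-level FWE is controlled under a null generator", {
  set.seed(54)
  nrun <- 120; ns <- 12
  any_sig <- logical(nrun)
  for (r in seq_len(nrun)) {
    a <- matrix(rnorm(ns * 64), ns)
    b <- matrix(rnorm(ns * 64), ns)
    res <- voxelwise_cluster_test(a, b, grid444, n_perm = 200, seed = r)
    any_sig[r] <- length(res$clusters) > 0
  }
  expect_lte(mean(any_sig), 0.05)   # nominal FWE 0.01, wide MC margin
})

test_that("ROI extraction averages the cube around the peak", {
  u <- activation_map(rep(7, 64), grid444)
  expect_equal(roi_extract(u, peak = 13), 7)              # uniform map
  set.seed(55)
  v <- rexp(64)
  amap <- activation_map(v, grid444)
  expect_equal(roi_extract(amap, 13, half_size = 1), v[13])  # cube < spacing

  # ROI of a smoothed delta is larger at the delta than far away
  interior <- which(apply(abs(grid444$positions), 1, max) <= 2.5)[1]
  delta <- numeric(64); delta[interior] <- 1
  smd <- smooth_and_log(activation_map(delta, grid444), fwhm = 10, log = FALSE)
  far <- which.max(rowSums((grid444$positions -
                              matrix(grid444$positions[interior, ], 64, 3,
                                     byrow = TRUE))^2))
  expect_gt(roi_extract(smd, interior, 7.5), roi_extract(smd, far, 7.5))
  expect_error(roi_extract(amap, 80), "off the grid")
})

test_that("repeated-measures ANOVA matches longhand sums of squares with GG", {
  set.seed(56)
  # identical values everywhere: all F = 0
  yconst <- array(5, c(6, 3, 2))
  tab0 <- rm_anova_gg(yconst)$table
  expect_true(all(tab0$F == 0 | is.nan(tab0$F)))

  # two-level one-factor: F = t^2
  y2 <- matrix(rnorm(10 * 2), 10)
  res2 <- rm_anova_gg(y2)
  tt <- t.test(y2[, 1], y2[, 2], paired = TRUE)$statistic
  expect_equal(res2$table$F[1], unname(tt)^2, tolerance = 1e-10)
  expect_equal(res2$table$gg_eps[1], 1)

  # random balanced two-way design vs the longhand oracle
  y <- array(rnorm(8 * 3 * 4), c(8, 3, 4)) +
    outer(rnorm(8), array(1, c(3, 4))) * 0.5    # subject effects
  dim(y) <- c(8, 3, 4)
  fit <- rm_anova_gg(y)$table
  oracle <- rm_anova_longhand(y)
  get <- function(eff) fit[fit$effect == eff, ]
  expect_equal(get("level")$F, oracle$A$F, tolerance = 1e-8)
  expect_equal(get("level")$df1, oracle$A$df1)
  expect_equal(get("level")$gg_eps, oracle$A$eps, tolerance = 1e-6)
  expect_equal(get("region")$F, oracle$B$F, tolerance = 1e-8)
  expect_equal(get("region")$gg_eps, oracle$B$eps, tolerance = 1e-6)
  expect_equal(get("level:region")$F, oracle$AB$F, tolerance = 1e-8)
  expect_equal(get("level:region")$gg_eps, oracle$AB$eps, tolerance = 1e-6)

  # GG-corrected p is the F tail at eps-scaled dfs
  lev <- get("level")
  expect_equal(lev$p_gg,
               pf(lev$F, lev$df1_gg, lev$df2_gg, lower.tail = FALSE),
               tolerance = 1e-8)

  expect_error(rm_anova_gg(array(c(NA, rnorm(23)), c(4, 3, 2))), "missing")
})
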