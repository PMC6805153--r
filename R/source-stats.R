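#' Neighbor-bin control map
#'
#' The control state for a target-frequency activation map: the voxelwise
#' average of the source maps at the two frequency bins adjacent to the
#' target bin.
#'
#' @param map_lo,map_hi [activation_map()]s at `f - delta` and `f + delta`
#'   on the same grid.
#' @return `activation_map` of the voxelwise mean.
#' @export
neighbor_control_map <- function(map_lo, map_hi) {
  stopifnot(inherits(map_lo, "activation_map"), inherits(map_hi, "activation_map"))
  if (!isTRUE(all.equal(map_lo$grid$positions, map_hi$grid$positions)))
    stopf("grid mismatch between neighbor maps")
  activation_map((map_lo$values + map_hi$values) / 2, map_lo$grid,
                 freq = mean(c(map_lo$freq, map_hi$freq)),
                 condition = map_lo$condition)
}

gaussian_kernel_matrix <- function(grid, fwhm) {
  sigma <- fwhm / 2.3548                     # FWHM -> sd of the Gaussian
  pos <- grid$positions
  n <- nrow(pos)
  d2 <- as.matrix(stats::dist(pos))^2
  K <- exp(-d2 / (2 * sigma^2))
  K[sqrt(d2) > 3.5 * sigma] <- 0             # compact support
  K / rowSums(K)                             # unit row sums conserve mass
}

#' Gaussian smoothing and log transform of an activation map
#'
#' Spatial smoothing with a Gaussian kernel of the given full width at
#' half maximum, computed on the native source grid from the grid
#' coordinates (`sigma = fwhm / 2.3548`; kernel rows normalized to sum 1
#' so a uniform map is preserved), followed by the natural log.  Minimum
#' L1-norm maps are sparse and strongly right skewed; the log transform
#' symmetrizes them before parametric voxelwise tests.  Zeros are floored
#' at `1e-12 * max(map)` before the log.
#'
#' @param map an [activation_map()] on the natural scale.
#' @param fwhm kernel FWHM in mm; 0 skips smoothing.
#' @param log apply the log transform (default `TRUE`).
#' @return transformed `activation_map` (with `log_transformed` set
#'   accordingly).
#' @export
smooth_and_log <- function(map, fwhm = 5, log = TRUE) {
  stopifnot(inherits(map, "activation_map"))
  if (map$log_transformed) stopf("map is already log transformed")
  v <- map$values
  if (fwhm > 0) v <- drop(gaussian_kernel_matrix(map$grid, fwhm) %*% v)
  if (log) {
    mx <- max(v)
    if (mx <= 0) {
      warnf("all-zero map: every value log-floored")
      mx <- 1
    }
    v <- base::log(pmax(v, 1e-12 * mx))
  }
  activation_map(v, map$grid, map$freq, map$condition, log_transformed = log)
}

## 26-neighborhood adjacency list on the cubic grid (Chebyshev distance
## <= spacing, excluding self)
grid_adjacency <- function(grid) {
  pos <- grid$positions
  n <- nrow(pos)
  tol <- grid$spacing * 1.01
  lapply(seq_len(n), function(i) {
    dd <- abs(sweep(pos, 2L, pos[i, ]))
    which(apply(dd, 1L, max) <= tol & seq_len(n) != i &
            apply(dd, 1L, max) > 0)
  })
}

## connected components of a voxel subset under a precomputed adjacency list
label_clusters <- function(supra, adj) {
  n <- length(supra)
  idx <- which(supra)
  if (!length(idx)) return(list())
  lab <- integer(n)
  comp <- list()
  for (seed in idx) {
    if (lab[seed]) next
    cur <- length(comp) + 1L
    queue <- seed
    lab[seed] <- cur
    members <- seed
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[v]]
      nb <- nb[supra[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        queue <- c(queue, nb)
        members <- c(members, nb)
      }
    }
    comp[[cur]] <- sort(members)
  }
  comp
}

paired_t_map <- function(D) {
  # D: subjects x voxels matrix of paired differences; vectorized t
  n <- nrow(D)
  m <- colMeans(D)
  s <- sqrt(colSums(sweep(D, 2L, m)^2) / (n - 1L))
  t <- m / (s / sqrt(n))
  t[s == 0 & m == 0] <- 0
  t[s == 0 & m > 0] <- Inf
  t[s == 0 & m < 0] <- -Inf
  t
}

#' Voxelwise paired t test with cluster-level FWE correction
#'
#' One-tailed paired t test (target > control) at every voxel, cluster
#' formation among supra-threshold voxels (voxel-level p below
#' `voxel_alpha`) under 26-neighborhood adjacency on the cubic grid, and
#' cluster-level family-wise error control by sign-flip permutation of the
#' paired differences with a maximum cluster-mass null distribution
#' (cluster mass = sum of member t values).  Clusters are retained at
#' cluster-level p below `cluster_alpha`.  With `s <= 11` subjects all
#' `2^s` sign assignments are enumerated; otherwise `n_perm` random flips
#' are drawn (the identity included).
#'
#' @param target_maps,control_maps subjects x voxels matrices (or lists of
#'   `activation_map`s), typically smoothed log maps.
#' @param grid the [source_grid()]; required when matrices are supplied.
#' @param voxel_alpha cluster-forming voxel-level threshold (one-tailed p,
#'   default 0.001).
#' @param cluster_alpha cluster-level FWE threshold (default 0.01).
#' @param n_perm number of sign-flip permutations (default 1024).
#' @param seed optional seed for the permutation draw.
#' @return object of class `cluster_result`: `voxel_t`, `df`,
#'   `t_threshold`, `clusters` (list of `voxels`, `peak`, `peak_t`,
#'   `mass`, `p_fwe`), `null_max_mass`, `n_perm`.  An empty cluster list
#'   means no supra-threshold voxel (not an error).
#' @export
voxelwise_cluster_test <- function(target_maps, control_maps, grid = NULL,
                                   voxel_alpha = 0.001, cluster_alpha = 0.01,
                                   n_perm = 1024L, seed = NULL) {
  as_mat <- function(x) {
    if (is.matrix(x)) return(x)
    grid <<- grid %||% x[[1L]]$grid
    do.call(rbind, lapply(x, function(mp) mp$values))
  }
  Tm <- as_mat(target_maps)
  Cm <- as_mat(control_maps)
  if (is.null(grid)) stopf("a source_grid is required with matrix input")
  if (!identical(dim(Tm), dim(Cm))) stopf("target/control dimensions differ")
  ns <- nrow(Tm)
  if (ns < 3L) stopf("need at least 3 paired subjects")
  D <- Tm - Cm
  df <- ns - 1L
  tobs <- paired_t_map(D)
  thr <- qt(1 - voxel_alpha, df)
  adj <- grid_adjacency(grid)
  obs_cl <- label_clusters(tobs > thr, adj)
  obs_mass <- vapply(obs_cl, function(v) sum(tobs[v]), numeric(1L))

  exhaustive <- ns <= 11L
  signs <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(1, -1)), ns)))
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    if (!is.null(seed)) set.seed(seed)
    rbind(rep(1, ns),
          matrix(sample(c(1, -1), (n_perm - 1L) * ns, replace = TRUE),
                 n_perm - 1L, ns))
  }
  null_max <- apply(signs, 1L, function(sg) {
    tp <- paired_t_map(D * sg)
    cl <- label_clusters(tp > thr, adj)
    if (!length(cl)) 0 else max(vapply(cl, function(v) sum(tp[v]), numeric(1L)))
  })
  pvals <- vapply(obs_mass, function(ms) mean(null_max >= ms - 1e-12), numeric(1L))
  keep <- order(obs_mass, decreasing = TRUE)
  clusters <- lapply(keep, function(j) {
    v <- obs_cl[[j]]
    list(voxels = v, peak = v[which.max(tobs[v])],
         peak_t = max(tobs[v]), mass = obs_mass[j], p_fwe = pvals[j])
  })
  clusters <- Filter(function(cl) cl$p_fwe < cluster_alpha, clusters)
  structure(list(voxel_t = tobs, df = df, t_threshold = thr,
                 clusters = clusters, null_max_mass = null_max,
                 n_perm = nrow(signs), exhaustive = exhaustive,
                 voxel_alpha = voxel_alpha, cluster_alpha = cluster_alpha,
                 grid = grid),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d voxels, df = %d, voxel t threshold %.3f\n",
              length(x$voxel_t), x$df, x$t_threshold))
  if (!length(x$clusters)) {
    cat("  no FWE-significant clusters\n")
  } else {
    for (i in seq_along(x$clusters)) {
      cl <- x$clusters[[i]]
      cat(sprintf("  cluster %d: %d voxels, peak t %.2f at voxel %d, mass %.1f, p_FWE %.4g\n",
                  i, length(cl$voxels), cl$peak_t, cl$peak, cl$mass, cl$p_fwe))
    }
  }
  invisible(x)
}

#' Extract the mean activation in a cubic ROI
#'
#' Averages the map over all grid points inside the cube of edge
#' `2 * half_size` centered at the peak voxel (default a 5 mm cube, which
#' on a 5 mm grid is the peak voxel itself).
#'
#' @param map an [activation_map()].
#' @param peak index of the center voxel.
#' @param half_size half edge length in mm (default 2.5).
#' @return scalar mean activation.
#' @export
roi_extract <- function(map, peak, half_size = 2.5) {
  stopifnot(inherits(map, "activation_map"))
  pos <- map$grid$positions
  if (peak < 1L || peak > nrow(pos)) stopf("peak voxel off the grid")
  dd <- abs(sweep(pos, 2L, pos[peak, ]))
  inside <- apply(dd, 1L, max) <= half_size + 1e-9
  if (!any(inside)) stopf("empty ROI cube")
  mean(map$values[inside])
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' One- or two-way fully within-subject ANOVA on a balanced design, with
#' Greenhouse-Geisser sphericity correction of every multi-df effect and
#' Bonferroni-corrected pairwise paired t tests across levels within each
#' region.  The univariate repeated-measures machinery is delegated to
#' `car::Anova` on a multivariate linear model.
#'
#' @param y 3-D array `subjects x levels x regions` (use a third extent of
#'   1 for a one-way design), or a subjects x levels matrix.
#' @return object of class `rm_anova`: `table` (data frame with `effect`,
#'   `F`, `df1`, `df2`, `gg_eps`, `df1_gg`, `df2_gg`, `p`, `p_gg`) and
#'   `posthoc` (Bonferroni-adjusted pairwise paired t tests of levels
#'   within regions).
#' @export
rm_anova_gg <- function(y) {
  if (is.matrix(y)) y <- array(y, c(dim(y), 1L))
  stopifnot(length(dim(y)) == 3L)
  if (anyNA(y)) stopf("design error: missing cells")
  ns <- dim(y)[1L]; nl <- dim(y)[2L]; nr <- dim(y)[3L]
  if (ns < 3L) stopf("need at least 3 subjects")
  if (nl < 2L) stopf("need at least 2 levels")
  Y <- matrix(y, ns, nl * nr)            # columns vary level fastest
  if (nr > 1L) {
    idata <- expand.grid(level = factor(seq_len(nl)),
                         region = factor(seq_len(nr)))
    idesign <- ~ level * region
  } else {
    idata <- data.frame(level = factor(seq_len(nl)))
    idesign <- ~ level
  }
  mod <- stats::lm(Y ~ 1)
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  effects <- setdiff(rownames(ut), "(Intercept)")
  adj <- s$pval.adjustments
  tab <- do.call(rbind, lapply(effects, function(e) {
    F <- ut[e, "F value"]; df1 <- ut[e, "num Df"]; df2 <- ut[e, "den Df"]
    eps <- if (!is.null(adj) && e %in% rownames(adj)) unname(adj[e, "GG eps"]) else 1
    pgg <- if (!is.null(adj) && e %in% rownames(adj)) unname(adj[e, "Pr(>F[GG])"])
           else ut[e, "Pr(>F)"]
    if (!is.finite(eps)) eps <- 1                 # 1-df effects need no correction
    if (!is.finite(pgg)) pgg <- unname(ut[e, "Pr(>F)"])
    data.frame(effect = e, F = unname(F), df1 = unname(df1), df2 = unname(df2),
               gg_eps = eps, df1_gg = eps * unname(df1), df2_gg = eps * unname(df2),
               p = unname(ut[e, "Pr(>F)"]), p_gg = pgg)
  }))
  posthoc <- NULL
  if (nl > 1L) {
    pairs <- combn(nl, 2L)
    rows <- list()
    for (r in seq_len(nr)) {
      for (j in seq_len(ncol(pairs))) {
        a <- pairs[1L, j]; b <- pairs[2L, j]
        st <- paired_t_stats(y[, a, r] - y[, b, r], "two")
        rows[[length(rows) + 1L]] <-
          data.frame(region = r, level_a = a, level_b = b, t = st$t,
                     df = st$df, p_raw = st$p, cohens_d = st$d)
      }
    }
    posthoc <- do.call(rbind, rows)
    posthoc$p_bonf <- pmin(1, posthoc$p_raw * nrow(posthoc))
  }
  structure(list(table = tab, posthoc = posthoc, n_subjects = ns,
                 n_levels = nl, n_regions = nr),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, digits = 4, ...) {
  cat(sprintf("<rm_anova> %d subjects, %d levels x %d regions (within-subject)\n",
              x$n_subjects, x$n_levels, x$n_regions))
  print.data.frame(x$table, digits = digits, row.names = FALSE)
  invisible(x)
}
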