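#' Cubic source grid
#'
#' A regular cubic lattice of candidate dipole locations, the source space
#' of the inverse problem.  Coordinates are in millimetres; the default
#' spacing is the 5 mm grid step used throughout the package.
#'
#' @param dims integer length-3: number of grid points along each axis, or a
#'   single count `n` (the grid is then the first `n` points of a near-cubic
#'   lattice).
#' @param spacing grid step in mm.
#' @param center centre the grid on the origin?
#' @return an object of class `source_grid` with elements `positions`
#'   (n x 3 matrix, mm), `spacing` and `dims`.
#' @export
source_grid <- function(dims = c(4L, 4L, 4L), spacing = 5, center = TRUE) {
  if (spacing <= 0) stopf("spacing must be positive")
  if (length(dims) == 1L) {
    side <- ceiling(dims^(1 / 3))
    full <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                  z = seq_len(side)))
    pos <- full[seq_len(dims), , drop = FALSE] * spacing
    dims3 <- c(side, side, side)
  } else {
    stopifnot(length(dims) == 3L, all(dims >= 1L))
    pos <- as.matrix(expand.grid(x = seq_len(dims[1L]), y = seq_len(dims[2L]),
                                 z = seq_len(dims[3L]))) * spacing
    dims3 <- as.integer(dims)
  }
  if (center) pos <- sweep(pos, 2L, colMeans(pos))
  dimnames(pos) <- list(NULL, c("x", "y", "z"))
  structure(list(positions = pos, spacing = spacing, dims = dims3),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d points, %.3g mm spacing\n",
              nrow(x$positions), x$spacing))
  invisible(x)
}

n_sources <- function(x) nrow(x$positions)

## sensors on a spherical cap above the grid; mirror-symmetric in x so that
## left/right hemisphere labels are meaningful and a symmetric geometry is
## available for lateralization null checks
sensor_shell <- function(grid, m_sensors, radius_factor = 2) {
  ext <- max(sqrt(rowSums(grid$positions^2)))
  r <- radius_factor * max(ext, grid$spacing) + 4 * grid$spacing
  half <- ceiling(m_sensors / 2)
  # low-discrepancy-ish deterministic placement on the upper right octant cap
  i <- seq_len(half)
  theta <- acos(1 - 0.8 * (i - 0.5) / half)       # polar angle from +z
  phi <- pi * (0.15 + 0.7 * ((i * 0.618034) %% 1)) - pi / 2
  right <- cbind(x = r * sin(theta) * abs(cos(phi)),
                 y = r * sin(theta) * sin(phi),
                 z = r * cos(theta))
  left <- right
  left[, "x"] <- -left[, "x"]
  pos <- rbind(right, left)[seq_len(m_sensors), , drop = FALSE]
  side <- rep(c("right", "left"), each = half)[seq_len(m_sensors)]
  side[abs(pos[, "x"]) < 1e-9] <- "midline"
  list(positions = pos, side = factor(side, levels = c("left", "midline", "right")))
}

#' Synthetic leadfield (gain matrix)
#'
#' Builds an m x (3 n) gain matrix mapping dipole moments (three Cartesian
#' orientations per grid point) to sensors, standing in for a boundary
#' element forward model.  Two generators are available:
#'
#' * `"random-incoherent"`: i.i.d. Gaussian gains with every source's
#'   m x 3 column block normalized to unit Frobenius norm.  Incoherent
#'   columns are the favourable regime for sparse recovery and make solver
#'   behaviour easy to reason about.
#' * `"spherical-shell"`: a quasi-magnetic dipole model on a spherical
#'   sensor shell: the block column for orientation `e` at source `p` seen
#'   by a sensor at `r` with outward normal `o` is `((e x (r - p)) . o) /
#'   |r - p|^3`, so gains fall off with distance squared and radial source
#'   components are nearly silent, as in magnetoencephalography.
#'
#' @param n_sources number of grid points (ignored when `grid` is given).
#' @param m_sensors number of sensors (>= 2).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param mode `"random-incoherent"` or `"spherical-shell"`.
#' @param grid optional [source_grid()]; default is a near-cubic lattice of
#'   `n_sources` points at 5 mm spacing.
#' @param spacing grid spacing in mm used when building the default grid.
#' @return an object of class `leadfield`: list with `gain` (m x 3n),
#'   `grid`, `sensor_positions` (m x 3), `side` (left/midline/right factor)
#'   and `mode`.
#' @export
make_leadfield <- function(n_sources = NULL, m_sensors, seed = 1L,
                           mode = c("random-incoherent", "spherical-shell"),
                           grid = NULL, spacing = 5) {
  mode <- match.arg(mode)
  if (m_sensors < 2L) stopf("invalid geometry: need at least 2 sensors (got %d)",
                            m_sensors)
  if (is.null(grid)) {
    if (is.null(n_sources) || n_sources < 1L)
      stopf("need n_sources >= 1 or an explicit grid")
    grid <- source_grid(n_sources, spacing = spacing)
  }
  n <- n_sources(grid)
  shell <- sensor_shell(grid, m_sensors)
  gain <- matrix(0, m_sensors, 3L * n)
  if (mode == "random-incoherent") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    gain <- matrix(rnorm(m_sensors * 3L * n), m_sensors, 3L * n)
    for (i in seq_len(n)) {
      idx <- (3L * (i - 1L) + 1L):(3L * i)
      gain[, idx] <- gain[, idx] / sqrt(sum(gain[, idx]^2))
    }
  } else {
    o <- shell$positions / sqrt(rowSums(shell$positions^2))
    for (i in seq_len(n)) {
      d <- sweep(shell$positions, 2L, grid$positions[i, ])  # m x 3, r - p
      dist3 <- pmax(sqrt(rowSums(d^2)), grid$spacing / 2)^3
      # columns: e_k x d for the three unit orientations, projected on o
      cx <- cbind(0 * d[, 1L], -d[, 3L], d[, 2L])   # e_x x d
      cy <- cbind(d[, 3L], 0 * d[, 1L], -d[, 1L])   # e_y x d
      cz <- cbind(-d[, 2L], d[, 1L], 0 * d[, 1L])   # e_z x d
      idx <- 3L * (i - 1L)
      gain[, idx + 1L] <- rowSums(cx * o) / dist3
      gain[, idx + 2L] <- rowSums(cy * o) / dist3
      gain[, idx + 3L] <- rowSums(cz * o) / dist3
    }
    gain <- gain / max(abs(gain))
  }
  if (any(rowSums(abs(gain)) == 0)) stopf("invalid geometry: all-zero sensor row")
  structure(list(gain = gain, grid = grid, sensor_positions = shell$positions,
                 side = shell$side, mode = mode, seed = as.integer(seed)),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d sensors x %d sources (mode: %s)\n",
              nrow(x$gain), n_sources(x$grid), x$mode))
  invisible(x)
}

## save/restore of .Random.seed so seeded generators do not disturb the
## caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

source_block <- function(lf, i) lf$gain[, (3L * (i - 1L) + 1L):(3L * i), drop = FALSE]

#' Reduce each source to its two dominant orientations
#'
#' For every grid point the m x 3 gain block is decomposed by SVD and
#' projected onto the right singular vectors of its two largest singular
#' values — the two dominant source directions.  The third direction
#' (nearly silent for quasi-radial sources) is discarded; the fraction of
#' squared gain it carried is recorded per source.
#'
#' Sign convention for determinism: each singular vector is flipped so that
#' its entry of largest absolute value (first such entry on ties) is
#' positive.  Singular values are taken in the LAPACK descending order, so
#' exact ties between the 2nd and 3rd singular value resolve to the first
#' of the tied vectors.
#'
#' @param lf a [make_leadfield()] object.
#' @return an object of class `reduced_leadfield`: `gain2` (m x 2n),
#'   `orientations` (n x 2 x 3 array: theta and phi unit vectors),
#'   `discarded_energy` (length n), plus the grid and sensor metadata.
#' @export
reduce_orientations <- function(lf) {
  stopifnot(inherits(lf, "leadfield"))
  n <- n_sources(lf$grid)
  m <- nrow(lf$gain)
  gain2 <- matrix(0, m, 2L * n)
  orient <- array(NA_real_, c(n, 2L, 3L),
                  dimnames = list(NULL, c("theta", "phi"), c("x", "y", "z")))
  disc <- numeric(n)
  for (i in seq_len(n)) {
    B <- source_block(lf, i)
    tot <- sum(B^2)
    if (tot == 0) stopf("degenerate source %d: all-zero gain block", i)
    sv <- svd(B, nu = 2L, nv = 3L)
    V <- sv$v[, 1:2, drop = FALSE]
    for (k in 1:2) {                      # deterministic sign fix
      j <- which.max(abs(V[, k]))
      if (V[j, k] < 0) V[, k] <- -V[, k]
    }
    gain2[, c(2L * i - 1L, 2L * i)] <- B %*% V
    orient[i, 1L, ] <- V[, 1L]
    orient[i, 2L, ] <- V[, 2L]
    disc[i] <- if (length(sv$d) >= 3L) sv$d[3L]^2 / tot else 0
  }
  structure(list(gain2 = gain2, orientations = orient,
                 discarded_energy = disc, grid = lf$grid,
                 sensor_positions = lf$sensor_positions, side = lf$side),
            class = "reduced_leadfield")
}

#' @export
print.reduced_leadfield <- function(x, ...) {
  cat(sprintf("<reduced_leadfield> %d sensors x %d sources x 2 orientations\n",
              nrow(x$gain2), n_sources(x$grid)))
  cat(sprintf("  median discarded orientation energy: %.3g\n",
              stats::median(x$discarded_energy)))
  invisible(x)
}

#' Depth weights for the minimum L1-norm penalty
#'
#' Minimum-norm inverses are biased toward superficial, high-gain sources;
#' penalizing each source by a power of its gain norm counteracts this.
#' The weight of source i is `||G_i||_F ^ gamma`, normalized to mean 1, so
#' `gamma = 0` recovers the unweighted estimator and larger `gamma` makes
#' deep (small-gain) sources comparatively cheaper to activate.
#'
#' @param lf a `leadfield` or `reduced_leadfield`.
#' @param gamma nonnegative exponent (default 1).
#' @return positive numeric vector of length n with mean 1.
#' @export
depth_weights <- function(lf, gamma = 1) {
  if (gamma < 0) stopf("gamma must be >= 0")
  G <- if (inherits(lf, "reduced_leadfield")) lf$gain2 else lf$gain
  k <- ncol(G) / n_sources(lf$grid)
  n <- n_sources(lf$grid)
  nrm <- vapply(seq_len(n), function(i) {
    sqrt(sum(G[, (k * (i - 1L) + 1L):(k * i)]^2))
  }, numeric(1L))
  if (any(nrm == 0)) stopf("degenerate source with zero gain norm")
  w <- nrm^gamma
  w / mean(w)
}
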