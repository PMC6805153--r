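# Independent oracles used to validate the package's estimators.  These are
# deliberately naive (enumeration, grid search, longhand sums of squares)
# and share no code with the implementation they check.

## Exact minimizer of  min sum(w_j |x_j|)  s.t.  A x = b  by enumerating
## every support of size <= nrow(A) and keeping the best exact-fit basic
## solution.  Valid because an optimal basic solution of the equivalent LP
## has at most M nonzeros.
l1_enum_oracle <- function(A, b, w) {
  M <- nrow(A); P <- ncol(A)
  best <- Inf
  for (k in seq_len(M)) {
    for (S in asplit(combn(P, k), 2L)) {
      AS <- A[, S, drop = FALSE]
      fit <- tryCatch(qr.solve(AS, b), error = function(e) NULL)
      if (is.null(fit)) next
      if (max(abs(AS %*% fit - b)) > 1e-8 * max(1, max(abs(b)))) next
      obj <- sum(w[S] * abs(fit))
      if (obj < best) best <- obj
    }
  }
  best
}

## Grid-search minimizer of the weighted group norm over the affine
## feasible set {u0 + N t}, for nullspaces of dimension <= 2, by iterative
## grid refinement.  u0 is the minimum-norm solution, N an orthonormal
## nullspace basis.
group_l1_grid_oracle <- function(A, b, w, gsize, rounds = 6, npts = 41) {
  sv <- svd(A, nu = nrow(A), nv = ncol(A))
  r <- sum(sv$d > 1e-10 * sv$d[1L])
  u0 <- sv$v[, 1:r, drop = FALSE] %*% ((t(sv$u[, 1:r, drop = FALSE]) %*% b) / sv$d[1:r])
  N <- sv$v[, -(1:r), drop = FALSE]
  d <- ncol(N)
  stopifnot(d >= 1, d <= 2)
  g0 <- cumsum(c(0, gsize[-length(gsize)]))
  objective <- function(U) {
    # U: P x K matrix of candidate solutions; returns K objectives
    out <- 0
    for (g in seq_along(gsize)) {
      idx <- g0[g] + seq_len(gsize[g])
      out <- out + w[g] * sqrt(colSums(U[idx, , drop = FALSE]^2))
    }
    out
  }
  R <- objective(matrix(u0, ncol = 1L)) / min(w) + 1  # safe search radius
  R <- max(R, sqrt(sum(u0^2)))
  center <- numeric(d)
  best_t <- center; best <- Inf
  for (round in seq_len(rounds)) {
    grid1 <- seq(-R, R, length.out = npts)
    Tm <- if (d == 1L) matrix(grid1, 1L) else
      t(as.matrix(expand.grid(grid1, grid1)))
    Tm <- Tm + center
    U <- matrix(u0, nrow = length(u0), ncol = ncol(Tm)) + N %*% Tm
    obj <- objective(U)
    j <- which.min(obj)
    if (obj[j] < best) { best <- obj[j]; best_t <- Tm[, j] }
    center <- best_t
    R <- R * 2.5 / (npts - 1)   # zoom around the incumbent
  }
  best
}

## Longhand two-way (or one-way) fully within-subject ANOVA with
## Greenhouse-Geisser epsilon from the eigenvalues of the covariance of
## orthonormal contrast scores.  y: subjects x levelsA x levelsB array.
rm_anova_longhand <- function(y) {
  if (length(dim(y)) == 2L) y <- array(y, c(dim(y), 1L))
  ns <- dim(y)[1L]; A <- dim(y)[2L]; B <- dim(y)[3L]
  m <- mean(y)
  m_s <- apply(y, 1L, mean); m_a <- apply(y, 2L, mean); m_b <- apply(y, 3L, mean)
  m_sa <- apply(y, c(1L, 2L), mean); m_sb <- apply(y, c(1L, 3L), mean)
  m_ab <- apply(y, c(2L, 3L), mean)
  gg_eps <- function(S, k) {
    lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    sum(lam)^2 / ((k - 1L) * sum(lam^2))
  }
  orth_contrasts <- function(k) {
    C <- stats::contr.helmert(k)
    qr.Q(qr(C))           # orthonormal columns spanning the contrast space
  }
  out <- list()
  # main effect A
  SSA <- ns * B * sum((m_a - m)^2)
  SSAS <- B * sum((m_sa - outer(m_s, m_a, "+") + m)^2)
  CA <- orth_contrasts(A)
  WA <- m_sa %*% CA
  out$A <- list(F = (SSA / (A - 1L)) / (SSAS / ((A - 1L) * (ns - 1L))),
                df1 = A - 1L, df2 = (A - 1L) * (ns - 1L),
                eps = if (A > 2L) gg_eps(stats::cov(WA), A) else 1)
  if (B > 1L) {
    SSB <- ns * A * sum((m_b - m)^2)
    SSBS <- A * sum((m_sb - outer(m_s, m_b, "+") + m)^2)
    CB <- orth_contrasts(B)
    WB <- m_sb %*% CB
    out$B <- list(F = (SSB / (B - 1L)) / (SSBS / ((B - 1L) * (ns - 1L))),
                  df1 = B - 1L, df2 = (B - 1L) * (ns - 1L),
                  eps = if (B > 2L) gg_eps(stats::cov(WB), B) else 1)
    inter <- sweep(sweep(m_ab, 1L, m_a), 2L, m_b) + m
    SSAB <- ns * sum(inter^2)
    resid <- y
    for (s in seq_len(ns)) for (a in seq_len(A)) for (b in seq_len(B))
      resid[s, a, b] <- y[s, a, b] - m_sa[s, a] - m_sb[s, b] - m_ab[a, b] +
        m_s[s] + m_a[a] + m_b[b] - m
    SSABS <- sum(resid^2)
    df1 <- (A - 1L) * (B - 1L)
    # contrast scores for the interaction: kron of the two contrast bases
    Ycell <- matrix(y, ns, A * B)            # level A varies fastest
    CAB <- kronecker(CB, CA)
    WAB <- Ycell %*% CAB
    out$AB <- list(F = (SSAB / df1) / (SSABS / (df1 * (ns - 1L))),
                   df1 = df1, df2 = df1 * (ns - 1L),
                   eps = if (df1 > 1L) gg_eps(stats::cov(WAB), df1 + 1L) else 1)
  }
  out
}

## deterministic tiny leadfield/epoch builders shared across test files
toy_leadfield <- function(n = 20, m = 8, seed = 3, mode = "random-incoherent") {
  make_leadfield(n_sources = n, m_sensors = m, seed = seed, mode = mode)
}

toy_epochs <- function(data) {
  # wraps a channels x time matrix as 1 subject x 1 trial epochs at 40 Hz
  sensor_epochs(array(data, c(1L, 1L, dim(data))), sfreq = 40, t0 = -0.5)
}

## small but fully structured simulation used by several tests
small_sim <- function(seed = 1, n_subjects = 8, n_trials = 5, noise_sd = 1,
                      sfreq = 40, m = 24, grid_dims = c(4, 4, 4)) {
  lf <- make_leadfield(grid = source_grid(grid_dims, 5), m_sensors = m,
                       seed = seed)
  cfg <- sim_config(seed = seed, n_subjects = n_subjects, n_trials = n_trials,
                    sfreq = sfreq, noise_sd = noise_sd)
  list(lf = lf, cfg = cfg, sim = simulate_meg(cfg, lf))
}

channel_avg_spectrum <- function(epochs, skip = 1.25, len = 11.25) {
  power_spectrum(crop_steady_state(average_erf(prewhiten(epochs)), skip, len))
}
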