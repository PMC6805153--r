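#' Frequency-domain minimum L1-norm source estimate at one bin
#'
#' Solves the convex second-order cone program at a single complex
#' frequency bin `K_f` of the sensor spectrum:
#'
#' \deqn{\min_{\Omega} \sum_{i=1}^{n} w_i
#'   \sqrt{(\omega^{\theta}_{i,re})^2 + (\omega^{\theta}_{i,im})^2 +
#'         (\omega^{\phi}_{i,re})^2  + (\omega^{\phi}_{i,im})^2}
#'   \quad \mathrm{s.t.}\; K_f = G\,\Omega_f}
#'
#' where `G` is the orientation-reduced m x 2n gain matrix, `w` the depth
#' weighting vector, and each grid point contributes a complex coefficient
#' pair (theta and phi orientations).  The group-L2 penalty makes the
#' objective rotation invariant within each source (no bias toward the
#' coordinate axes), and the L1 structure across sources yields sparse
#' maps.  The complex equality constraint is split into stacked real and
#' imaginary linear constraints and the program is solved by an ADMM
#' method with a projection x-update, so the returned coefficients satisfy
#' the equality constraint to machine precision.  With `noise_tol` the
#' equality is relaxed to `||K_f - G Omega||_2 <= noise_tol`.
#'
#' @param kf complex sensor vector at the target bin (length m).
#' @param rlf a [reduce_orientations()] reduced leadfield.
#' @param weights depth weights (length n, positive); default
#'   `depth_weights(rlf, gamma)`.
#' @param gamma depth-weighting exponent used when `weights` is `NULL`.
#' @param noise_tol `NULL` for the equality-constrained program (default);
#'   a positive scalar for the relaxed epsilon-cone, or `"auto"` for
#'   `1e-6 * ||K_f||`.
#' @param freq optional frequency label (Hz) carried on the fit.
#' @param max_iter,tol_rel,tol_abs ADMM iteration cap and relative /
#'   absolute stopping tolerances.
#' @return an object of class `l1fit` with elements `omega` (n x 2
#'   complex matrix, columns theta/phi), `group_norms`, `objective`
#'   (evaluated exactly on `omega`), `residual_norm`, `weights`, `freq`,
#'   `converged`, `iterations`.  Methods: `print`, `coef`, `fitted`,
#'   `residuals`.
#' @seealso [rms_activation()] to turn a fit into an activation map.
#' @export
solve_l1_bin <- function(kf, rlf, weights = NULL, gamma = 1,
                         noise_tol = NULL, freq = NA_real_,
                         max_iter = 30000L, tol_rel = 1e-7, tol_abs = 1e-10) {
  stopifnot(inherits(rlf, "reduced_leadfield"))
  m <- nrow(rlf$gain2)
  n <- ncol(rlf$gain2) / 2L
  if (length(kf) != m)
    stopf("K_f has length %d but the leadfield has %d sensors", length(kf), m)
  kf <- as.complex(kf)
  if (any(!is.finite(Re(kf))) || any(!is.finite(Im(kf)))) stopf("K_f must be finite")
  w <- weights %||% depth_weights(rlf, gamma)
  if (length(w) != n || any(w <= 0)) stopf("weights must be %d positive values", n)

  # column order: per source the 4 real coefficients (theta_re, phi_re,
  # theta_im, phi_im); constraints stack Re over Im
  A <- matrix(0, 2L * m, 4L * n)
  for (i in seq_len(n)) {
    cols <- rlf$gain2[, c(2L * i - 1L, 2L * i), drop = FALSE]
    A[seq_len(m), 4L * (i - 1L) + 1:2] <- cols
    A[m + seq_len(m), 4L * (i - 1L) + 3:4] <- cols
  }
  b <- c(Re(kf), Im(kf))
  eps <- if (is.null(noise_tol)) -1
         else if (identical(noise_tol, "auto")) 1e-6 * sqrt(sum(Mod(kf)^2))
         else as.numeric(noise_tol)

  if (all(b == 0)) {
    sol <- list(x = numeric(4L * n), objective = 0, residual = 0,
                iterations = 0L, converged = TRUE)
  } else {
    sol <- .admm_group_bp(A, b, rep(4L, n), w, eps, rho_init = 1,
                          alpha = 1.7, max_iter = as.integer(max_iter),
                          tol_abs = tol_abs, tol_rel = tol_rel)
    if (!sol$converged)
      warnf("ADMM reached max_iter = %d without meeting tolerances", max_iter)
  }
  x <- matrix(sol$x, nrow = 4L)                      # 4 x n
  omega <- cbind(theta = complex(real = x[1L, ], imaginary = x[3L, ]),
                 phi = complex(real = x[2L, ], imaginary = x[4L, ]))
  gn <- sqrt(colSums(x^2))
  structure(list(omega = omega, group_norms = gn,
                 objective = sum(w * gn), residual_norm = sol$residual,
                 weights = w, freq = freq, noise_tol = if (eps > 0) eps else NULL,
                 converged = sol$converged, iterations = sol$iterations,
                 rlf = rlf, kf = kf, call = match.call()),
            class = "l1fit")
}

#' @export
print.l1fit <- function(x, ...) {
  n <- nrow(x$omega)
  act <- sum(x$group_norms > 1e-6 * max(x$group_norms, 1e-300))
  cat(sprintf("<l1fit> minimum L1-norm source estimate%s\n",
              if (is.na(x$freq)) "" else sprintf(" at %.4g Hz", x$freq)))
  cat(sprintf("  %d sources, %d active groups (> 1e-6 of max norm)\n", n, act))
  cat(sprintf("  objective %.6g, constraint residual %.3g, %d ADMM iterations%s\n",
              x$objective, x$residual_norm, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
coef.l1fit <- function(object, ...) object$omega

#' @export
fitted.l1fit <- function(object, ...) {
  G <- object$rlf$gain2
  n <- nrow(object$omega)
  om <- as.vector(t(object$omega))        # theta1, phi1, theta2, ...
  drop(G %*% Re(om)) + 1i * drop(G %*% Im(om))
}

#' @export
residuals.l1fit <- function(object, ...) object$kf - fitted(object)

#' RMS activation map of a source fit
#'
#' The scalar activation of each grid point is the root mean square of the
#' four real solution components (real and imaginary parts of the two
#' orientation coefficients): `sqrt((o_th_re^2 + o_th_im^2 + o_ph_re^2 +
#' o_ph_im^2) / 4)`, i.e. `group_norm / 2`.  The RMS-over-4 convention is
#' a fixed global factor and cancels in every contrast.  The map is
#' invariant to a global phase rotation of `K_f`.
#'
#' @param sol an [solve_l1_bin()] fit.
#' @return object of class `activation_map`: `values` (length n,
#'   nonnegative), `freq`, `grid`, `log_transformed = FALSE`.
#' @export
rms_activation <- function(sol) {
  stopifnot(inherits(sol, "l1fit"))
  activation_map(sol$group_norms / 2, grid = sol$rlf$grid, freq = sol$freq)
}

#' Estimate the single-bin noise scale from off-peak bins
#'
#' For noise-aware source mapping, the expected norm of the noise
#' component of `K_f` is estimated as the median L2 norm of the complex
#' sensor spectrum over the bins of the band of interest that are not
#' tagged (and not adjacent to a tagged bin).  Under the null those bins
#' contain the same noise process as the target bin, so their typical
#' norm is a direct plug-in for the `noise_tol` of [solve_l1_bin()]:
#' the relaxed program then only explains the structure rising above the
#' noise floor, which concentrates the solution instead of forcing it to
#' reproduce every noisy sensor value exactly.
#'
#' @param X complex spectrum matrix, bins x sensors (e.g. `mvfft` of the
#'   windowed evoked divided by the window length).
#' @param freqs bin-center frequencies for the rows of `X`.
#' @param band band of interest (Hz).
#' @param exclude tagged frequencies whose bins (and immediate neighbors)
#'   are left out of the estimate.
#' @return scalar noise tolerance (L2 norm across sensors).
#' @export
estimate_noise_tol <- function(X, freqs, band = c(0.5, 4.5),
                               exclude = c(0.8, 4)) {
  stopifnot(is.complex(X) || is.numeric(X))
  spacing <- freqs[2L] - freqs[1L]
  sel <- freqs >= band[1L] - 1e-9 & freqs <= band[2L] + 1e-9
  for (f in exclude) sel <- sel & abs(freqs - f) > 1.5 * spacing - 1e-9
  if (sum(sel) < 3L) stopf("need at least 3 off-peak bins")
  stats::median(sqrt(rowSums(Mod(X[sel, , drop = FALSE])^2)))
}

#' Construct an activation map
#'
#' @param values nonnegative numeric vector, one per grid point (on the
#'   natural scale; see [smooth_and_log()]).
#' @param grid the [source_grid()] the values live on.
#' @param freq frequency label (Hz).
#' @param condition condition label.
#' @param log_transformed has the natural log already been applied?
#' @return object of class `activation_map`.
#' @export
activation_map <- function(values, grid, freq = NA_real_,
                           condition = NA_character_, log_transformed = FALSE) {
  stopifnot(inherits(grid, "source_grid"))
  if (length(values) != n_sources(grid))
    stopf("map has %d values but grid has %d points", length(values),
          n_sources(grid))
  if (!log_transformed && any(values < 0)) stopf("activation must be nonnegative")
  structure(list(values = as.numeric(values), grid = grid, freq = freq,
                 condition = condition, log_transformed = log_transformed),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> %d voxels%s%s; peak %.4g at voxel %d\n",
              length(x$values),
              if (is.na(x$freq)) "" else sprintf(", %.4g Hz", x$freq),
              if (x$log_transformed) " (log scale)" else "",
              max(x$values), which.max(x$values)))
  invisible(x)
}
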