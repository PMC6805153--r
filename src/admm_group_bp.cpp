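// ADMM solver for the weighted group basis-pursuit problem
//
//   minimize    sum_g  w_g * || u_g ||_2
//   subject to  A u = b                       (equality mode, eps <= 0)
//          or   || A u - b ||_2 <= eps        (relaxed mode,  eps  > 0)
//
// Columns of A must be ordered so that groups are contiguous; `gsize`
// gives the number of columns in each group.  This is the computational
// core of the frequency-domain minimum L1-norm source estimate: the
// complex single-bin constraint K_f = G Omega_f is split by the caller
// into stacked real and imaginary linear constraints, and each source
// contributes one group of four real coefficients (theta/phi x re/im).
//
// Equality mode uses the projection form of ADMM for basis pursuit
// (x-update projects onto the affine set, so the returned `x` iterate is
// feasible to machine precision); relaxed mode adds a slack variable
// projected onto the eps-ball.  Over-relaxation and residual-balancing
// rho adaptation are standard.

#include <RcppArmadillo.h>
using namespace arma;

static void group_shrink(vec &z, const vec &v, const uvec &g0,
                         const uvec &glen, const vec &kappa) {
  const uword n = g0.n_elem;
  for (uword g = 0; g < n; ++g) {
    const uword a = g0[g], len = glen[g];
    double nrm = 0.0;
    for (uword j = 0; j < len; ++j) nrm += v[a + j] * v[a + j];
    nrm = std::sqrt(nrm);
    const double scale = (nrm > kappa[g]) ? (1.0 - kappa[g] / nrm) : 0.0;
    for (uword j = 0; j < len; ++j) z[a + j] = scale * v[a + j];
  }
}

static double group_objective(const vec &x, const uvec &g0,
                              const uvec &glen, const vec &w) {
  double obj = 0.0;
  for (uword g = 0; g < g0.n_elem; ++g) {
    double nrm = 0.0;
    for (uword j = 0; j < glen[g]; ++j) nrm += x[g0[g] + j] * x[g0[g] + j];
    obj += w[g] * std::sqrt(nrm);
  }
  return obj;
}

// [[Rcpp::export(name = ".admm_group_bp")]]
Rcpp::List admm_group_bp(const arma::mat &A, const arma::vec &b,
                         const arma::ivec &gsize, const arma::vec &w,
                         const double eps, const double rho_init,
                         const double alpha, const int max_iter,
                         const double tol_abs, const double tol_rel) {
  const uword M = A.n_rows, P = A.n_cols, n = gsize.n_elem;
  uvec g0(n), glen(n);
  {
    uword off = 0;
    for (uword g = 0; g < n; ++g) {
      g0[g] = off;
      glen[g] = (uword)gsize[g];
      off += glen[g];
    }
    if (off != P) Rcpp::stop("group sizes do not sum to ncol(A)");
  }

  double rho = rho_init > 0 ? rho_init : 1.0;
  vec x(P, fill::zeros), z(P, fill::zeros), u(P, fill::zeros);
  vec zold(P), kappa(n);
  const double sqrtP = std::sqrt((double)P);
  bool converged = false;
  int iter = 0;

  if (eps <= 0.0) {
    // equality mode: x-update is projection onto {x : A x = b}
    mat AAt = A * A.t();
    AAt.diag() += 1e-12 * trace(AAt) / M;  // guards exact rank loss only
    mat R;
    if (!chol(R, AAt)) Rcpp::stop("A A' is not positive definite");
    // cache A' (AA')^{-1} b for the constant part of the projection
    vec pb = solve(trimatu(R), solve(trimatl(R.t()), b));
    vec xb = A.t() * pb;

    for (iter = 1; iter <= max_iter; ++iter) {
      vec v = z - u;
      vec Av = A * v;
      x = v - A.t() * solve(trimatu(R), solve(trimatl(R.t()), Av)) + xb;
      vec xh = alpha * x + (1.0 - alpha) * z;
      zold = z;
      kappa = w / rho;
      group_shrink(z, xh + u, g0, glen, kappa);
      u += xh - z;

      const double rnorm = norm(x - z);
      const double snorm = rho * norm(z - zold);
      const double eps_pri =
          sqrtP * tol_abs + tol_rel * std::max(norm(x), norm(z));
      const double eps_dua = sqrtP * tol_abs + tol_rel * rho * norm(u);
      if (rnorm < eps_pri && snorm < eps_dua) { converged = true; break; }
      if (iter % 25 == 0) {
        if (rnorm > 10.0 * snorm)      { rho *= 2.0; u /= 2.0; }
        else if (snorm > 10.0 * rnorm) { rho /= 2.0; u *= 2.0; }
      }
    }
    // x is feasible (projection); report the solution and objective on x
    const double obj = group_objective(x, g0, glen, w);
    return Rcpp::List::create(
        Rcpp::Named("x") = x, Rcpp::Named("objective") = obj,
        Rcpp::Named("residual") = norm(A * x - b),
        Rcpp::Named("iterations") = iter, Rcpp::Named("converged") = converged,
        Rcpp::Named("rho") = rho);
  }

  // relaxed mode: splitting x / (z, s) with s = A x - b, ||s|| <= eps.
  // (I + A'A)^{-1} is applied through the Woodbury identity so only an
  // M x M factor is needed.
  mat S = A * A.t();
  S.diag() += 1.0;
  mat R;
  if (!chol(R, S)) Rcpp::stop("I + AA' is not positive definite");
  vec s(M, fill::zeros), u2(M, fill::zeros);

  for (iter = 1; iter <= max_iter; ++iter) {
    vec rhs = (z - u) + A.t() * (b + s - u2);
    vec Ar = A * rhs;
    x = rhs - A.t() * solve(trimatu(R), solve(trimatl(R.t()), Ar));
    zold = z;
    kappa = w / rho;
    group_shrink(z, x + u, g0, glen, kappa);
    vec Axb = A * x - b;
    vec v2 = Axb + u2;
    const double vn = norm(v2);
    s = (vn > eps) ? vec(v2 * (eps / vn)) : v2;
    u += x - z;
    u2 += Axb - s;

    const double r1 = norm(x - z), r2 = norm(Axb - s);
    const double rnorm = std::sqrt(r1 * r1 + r2 * r2);
    const double snorm = rho * norm(z - zold);
    const double eps_pri =
        sqrtP * tol_abs + tol_rel * std::max(norm(x), norm(z) + norm(s));
    const double nu1 = norm(u), nu2 = norm(u2);
    const double eps_dua =
        sqrtP * tol_abs + tol_rel * rho * std::sqrt(nu1 * nu1 + nu2 * nu2);
    if (rnorm < eps_pri && snorm < eps_dua) { converged = true; break; }
    if (iter % 25 == 0) {
      if (rnorm > 10.0 * snorm)      { rho *= 2.0; u /= 2.0; u2 /= 2.0; }
      else if (snorm > 10.0 * rnorm) { rho /= 2.0; u *= 2.0; u2 *= 2.0; }
    }
  }
  const double obj = group_objective(z, g0, glen, w);
  return Rcpp::List::create(
      Rcpp::Named("x") = z, Rcpp::Named("objective") = obj,
      Rcpp::Named("residual") = norm(A * z - b),
      Rcpp::Named("iterations") = iter, Rcpp::Named("converged") = converged,
      Rcpp::Named("rho") = rho);
}
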