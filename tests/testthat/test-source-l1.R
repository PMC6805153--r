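test_that("orientation reduction matches the best rank-2 approximation", {
  set.seed(41)
  lf <- toy_leadfield(n = 6, m = 10, seed = 8)
  rlf <- reduce_orientations(lf)
  for (i in 1:6) {
    B <- lf$gain[, (3 * i - 2):(3 * i)]
    sv <- svd(B)
    # reconstruction error on the reduced basis equals the 3rd singular value
    V <- cbind(rlf$orientations[i, 1, ], rlf$orientations[i, 2, ])
    recon <- rlf$gain2[, (2 * i - 1):(2 * i)] %*% t(V)
    expect_equal(norm(B - recon, "F"), sv$d[3], tolerance = 1e-9)
    expect_equal(rlf$discarded_energy[i], sv$d[3]^2 / sum(sv$d^2),
                 tolerance = 1e-12)
    # orientation pair is orthonormal
    expect_equal(crossprod(V), diag(2), tolerance = 1e-12)
  }

  # exact rank-2 block: reduction reproduces it with no discarded energy
  lf2 <- toy_leadfield(n = 1, m = 5, seed = 2)
  B <- lf2$gain
  B[, 3] <- B[, 1] + B[, 2]                  # rank 2 by construction
  lf2$gain <- B
  r2 <- reduce_orientations(lf2)
  V <- cbind(r2$orientations[1, 1, ], r2$orientations[1, 2, ])
  expect_equal(r2$gain2 %*% t(V), B, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(r2$discarded_energy[1], 0, tolerance = 1e-12)

  # determinism across repeated calls
  ra <- reduce_orientations(lf)
  rb <- reduce_orientations(lf)
  expect_identical(ra$gain2, rb$gain2)

  lf3 <- toy_leadfield(n = 2, m = 4, seed = 3)
  lf3$gain[, 1:3] <- 0
  expect_error(reduce_orientations(lf3), "degenerate source 1")
})

test_that("depth weights follow the gain-norm power law", {
  lf <- toy_leadfield(n = 5, m = 6, seed = 4)
  expect_equal(depth_weights(lf, gamma = 0), rep(1, 5))

  # two sources with block norms 1 and 4 at gamma = 1 -> (0.4, 1.6)
  lf2 <- toy_leadfield(n = 2, m = 6, seed = 5)
  lf2$gain[, 4:6] <- lf2$gain[, 4:6] * 4 / sqrt(sum(lf2$gain[, 4:6]^2))
  lf2$gain[, 1:3] <- lf2$gain[, 1:3] / sqrt(sum(lf2$gain[, 1:3]^2))
  expect_equal(depth_weights(lf2, gamma = 1), c(0.4, 1.6), tolerance = 1e-12)
  expect_error(depth_weights(lf, gamma = -1), "gamma")
})

test_that("depth weighting rescues a deep source that gamma = 0 mislocalizes", {
  # constructed two-source instance: the deep source (gain 0.2) generates
  # the data; the superficial source shares its dominant plane (in-plane
  # rotated) with gain 4.5 plus a data-silent third direction that only
  # inflates its gain norm.  The unweighted estimator buys the cheap
  # high-gain superficial representation; gain-norm weights (gamma = 1)
  # make it uneconomical and recover the true deep support.
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    U1 <- q[, 1:2]; u3 <- q[, 3]
    th <- 0.3; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    lf <- toy_leadfield(n = 2, m = 3, seed = 1)
    lf$gain <- cbind(cbind(0.2 * U1, 1e-3 * u3),      # deep block
                     cbind(4.5 * U1 %*% R, 3 * u3))   # superficial block
    rlf <- reduce_orientations(lf)
    kf <- complex(real = drop(0.2 * U1 %*% c(1, 0.5)), imaginary = 0)
    gn0 <- suppressWarnings(
      solve_l1_bin(kf, rlf, weights = depth_weights(lf, 0),
                   max_iter = 60000)$group_norms)
    gn1 <- suppressWarnings(
      solve_l1_bin(kf, rlf, weights = depth_weights(lf, 1),
                   max_iter = 60000)$group_norms)
    expect_equal(which.max(gn0), 2L)   # unweighted: superficial source wins
    expect_equal(which.max(gn1), 1L)   # depth-weighted: deep source wins
  }
})

test_that("solver handles zero data and respects the scaling covariance", {
  lf <- toy_leadfield(n = 10, m = 5, seed = 7)
  rlf <- reduce_orientations(lf)
  z <- solve_l1_bin(rep(0 + 0i, 5), rlf)
  expect_equal(z$objective, 0)
  expect_true(all(z$group_norms == 0))

  set.seed(43)
  kf <- complex(real = rnorm(5), imaginary = rnorm(5))
  f1 <- solve_l1_bin(kf, rlf)
  f3 <- solve_l1_bin(3 * kf, rlf)
  expect_equal(f3$objective / f1$objective, 3, tolerance = 1e-5)
  expect_equal(f3$group_norms, 3 * f1$group_norms, tolerance = 1e-4)
  expect_equal(rms_activation(f3)$values, 3 * rms_activation(f1)$values,
               tolerance = 1e-4)
})

test_that("noiseless single-source data are recovered with exact support", {
  # oracle: enumerate single-source least-squares fits; only the true
  # source can explain the data exactly
  set.seed(44)
  for (rep in 1:10) {
    lf <- toy_leadfield(n = 20, m = 8, seed = 100 + rep)
    rlf <- reduce_orientations(lf)
    true_src <- sample(20, 1)
    om <- complex(real = rnorm(2), imaginary = rnorm(2))
    cols <- rlf$gain2[, (2 * true_src - 1):(2 * true_src)]
    kf <- drop(cols %*% Re(om)) + 1i * drop(cols %*% Im(om))

    exact_fits <- vapply(1:20, function(i) {
      ci <- rlf$gain2[, (2 * i - 1):(2 * i)]
      re <- qr.solve(ci, Re(kf)); im <- qr.solve(ci, Im(kf))
      max(abs(ci %*% re - Re(kf)), abs(ci %*% im - Im(kf)))
    }, numeric(1))
    expect_equal(which(exact_fits < 1e-8), true_src)   # oracle: unique fit

    fit <- solve_l1_bin(kf, rlf, weights = rep(1, 20))
    gn <- fit$group_norms
    expect_equal(which.max(gn), true_src)
    expect_lt(max(gn[-true_src]), 1e-6 * max(gn))
    expect_equal(Mod(coef(fit)[true_src, ]), Mod(om), tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})

test_that("solver objective matches independent enumeration and grid oracles", {
  set.seed(45)
  # scalar groups (size-1): exact enumeration over supports
  for (rep in 1:8) {
    M <- sample(3:5, 1); P <- sample(7:10, 1)
    A <- matrix(rnorm(M * P), M)
    b <- rnorm(M)
    w <- runif(P, 0.5, 2)
    sol <- freqtag:::.admm_group_bp(A, b, rep(1L, P), w, -1, 1, 1.7, 30000L,
                                    1e-10, 1e-8)
    expect_lt(abs(sol$objective - l1_enum_oracle(A, b, w)) /
                l1_enum_oracle(A, b, w), 1e-5)
    expect_lt(sol$residual, 1e-8 * max(1, sqrt(sum(b^2))))
  }

  # complex 4-groups with a 2-dimensional feasible manifold: grid search
  for (rep in 1:6) {
    lf <- toy_leadfield(n = 3, m = 5, seed = 200 + rep)
    rlf <- reduce_orientations(lf)
    kf <- complex(real = rnorm(5), imaginary = rnorm(5))
    w <- depth_weights(rlf, 1)
    fit <- solve_l1_bin(kf, rlf, weights = w)
    A <- matrix(0, 10, 12)
    for (i in 1:3) {
      cols <- rlf$gain2[, (2 * i - 1):(2 * i)]
      A[1:5, 4 * i - 3:2] <- cols
      A[6:10, 4 * i - 1:0] <- cols
    }
    oracle <- group_l1_grid_oracle(A, c(Re(kf), Im(kf)), w, rep(4L, 3))
    expect_lt(abs(fit$objective - oracle) / oracle, 1e-4)
  }
})

test_that("tiny real instance matches a 1-D brute-force search", {
  # m = 2 sensors, n = 3 single-orientation sources, real data: the
  # feasible set of the scalar-group problem is a 1-D affine line
  set.seed(46)
  A <- matrix(rnorm(6), 2, 3)
  b <- rnorm(2)
  w <- rep(1, 3)
  sol <- freqtag:::.admm_group_bp(A, b, rep(1L, 3), w, -1, 1, 1.7, 30000L,
                                  1e-10, 1e-8)
  oracle <- group_l1_grid_oracle(A, b, w, rep(1L, 3))
  expect_lt(abs(sol$objective - oracle) / oracle, 1e-4)
})

test_that("solutions certify optimality and vertex sparsity", {
  set.seed(47)
  lf <- toy_leadfield(n = 20, m = 8, seed = 9)
  rlf <- reduce_orientations(lf)
  w <- depth_weights(rlf, 1)
  kf <- complex(real = rnorm(8), imaginary = rnorm(8))
  fit <- solve_l1_bin(kf, rlf, weights = w)

  # feasible perturbations never decrease the objective (convexity check)
  A <- matrix(0, 16, 80)
  for (i in 1:20) {
    cols <- rlf$gain2[, (2 * i - 1):(2 * i)]
    A[1:8, 4 * i - 3:2] <- cols
    A[9:16, 4 * i - 1:0] <- cols
  }
  NS <- svd(A, nv = 80)$v[, 17:80]
  x0 <- numeric(80)
  om <- coef(fit)
  for (i in 1:20) x0[4 * i - 3:0] <- c(Re(om[i, ]), Im(om[i, ]))
  objf <- function(x) sum(w * sqrt(colSums(matrix(x, 4)^2)))
  base_obj <- objf(x0)
  expect_equal(base_obj, fit$objective, tolerance = 1e-10)
  for (k in 1:20) {
    dvec <- NS %*% rnorm(64)
    dvec <- dvec / sqrt(sum(dvec^2))
    for (delta in c(1e-3, -1e-3)) {
      expect_gte(objf(x0 + delta * dvec), base_obj - 1e-7 * base_obj)
    }
  }

  # vertex solutions: the complex bin splits into 2m real constraints, so
  # at most 2m groups can be active at an extreme point
  expect_lte(sum(fit$group_norms > 1e-6 * max(fit$group_norms)), 16)
})

test_that("relaxed epsilon-cone mode trades residual for objective", {
  set.seed(48)
  lf <- toy_leadfield(n = 12, m = 6, seed = 10)
  rlf <- reduce_orientations(lf)
  kf <- complex(real = rnorm(6), imaginary = rnorm(6))
  eq <- solve_l1_bin(kf, rlf)
  eps <- 0.2 * sqrt(sum(Mod(kf)^2))
  rel <- solve_l1_bin(kf, rlf, noise_tol = eps)
  expect_lte(rel$residual_norm, eps * 1.01)
  expect_lt(rel$objective, eq$objective)   # slack can only cheapen the fit
})

test_that("RMS activation uses the four-component convention and is phase invariant", {
  lf <- toy_leadfield(n = 3, m = 6, seed = 11)
  rlf <- reduce_orientations(lf)
  fit <- solve_l1_bin(rep(0 + 0i, 6), rlf)
  fit$group_norms <- c(2, 0, 0)            # single component = 2 after packing
  expect_equal(rms_activation(fit)$values, c(1, 0, 0))

  set.seed(49)
  kf <- complex(real = rnorm(6), imaginary = rnorm(6))
  base <- rms_activation(solve_l1_bin(kf, rlf))$values
  for (alpha in c(0.7, 2.1, 4.4)) {
    rot <- rms_activation(solve_l1_bin(exp(1i * alpha) * kf, rlf))$values
    expect_equal(rot, base, tolerance = 1e-4)
  }
})
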