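test_that("pre-whitening divides by the baseline SD and is scale invariant", {
  set.seed(21)
  nch <- 3; nt <- 104; npre <- 20
  data <- array(rnorm(2 * nch * nt), c(1, 2, nch, nt))
  data[1, , 1, 1:npre] <- data[1, , 1, 1:npre] * 2    # baseline SD ~2
  data[1, , 2, 1:npre] <- data[1, , 2, 1:npre] * 0.5
  ep <- sensor_epochs(data, sfreq = 40, t0 = -0.5)
  wh <- prewhiten(ep)
  sds <- attr(wh, "baseline_sd")
  for (ch in 1:nch) {
    expect_equal(wh$data[1, , ch, ], ep$data[1, , ch, ] / sds[1, ch])
    expect_equal(sd(as.vector(wh$data[1, , ch, 1:npre])), 1, tolerance = 1e-12)
  }
  # rescaling a channel before whitening changes nothing after
  ep10 <- ep
  ep10$data[1, , 2, ] <- ep10$data[1, , 2, ] * 10
  expect_equal(prewhiten(ep10)$data, wh$data, tolerance = 1e-12)

  flat <- ep
  flat$data[1, , 3, 1:npre] <- 0
  expect_error(prewhiten(flat), "channel 3")
})

test_that("evoked averaging is the arithmetic mean with the expected noise reduction", {
  set.seed(22)
  x <- array(rnorm(1 * 1 * 2 * 60), c(1, 1, 2, 60))
  ep1 <- sensor_epochs(x, 40, -0.5)
  expect_equal(average_erf(ep1)$data[1, , ], x[1, 1, , ])   # single trial: identity

  x2 <- array(0, c(1, 2, 2, 60))
  x2[1, 1, , ] <- x[1, 1, , ]
  x2[1, 2, , ] <- -x[1, 1, , ]
  expect_equal(max(abs(average_erf(sensor_epochs(x2, 40, -0.5))$data)), 0)

  # variance of the evoked noise ~ single-trial variance / n_trials
  nrep <- 300; nt <- 15
  v1 <- vv <- numeric(nrep)
  for (r in seq_len(nrep)) {
    noise <- array(rnorm(nt * 50), c(1, nt, 1, 50))
    ev <- average_erf(sensor_epochs(noise, 40, -0.5))
    vv[r] <- var(as.vector(ev$data))
  }
  expect_equal(mean(vv), 1 / nt, tolerance = 0.05)
})

test_that("steady-state cropping implements the transient-exclusion window", {
  ep <- sensor_epochs(array(rnorm(1 * 1 * 1 * 520), c(1, 1, 1, 520)), 40, -0.5)
  erf <- average_erf(ep)
  ss <- crop_steady_state(erf)                      # defaults 1.25 + 11.25 s
  expect_equal(dim(ss$data)[3], 450L)               # 11.25 s at 40 Hz
  expect_equal(attr(ss, "actual_length"), 11.25)
  expect_equal(ss$t0, 1.25)

  s0 <- crop_steady_state(erf, skip = 0, length = 2)
  onset_sample <- round(0.5 * 40) + 1
  expect_equal(s0$data[1, 1, 1], erf$data[1, 1, onset_sample])

  # non-integer sample count is rounded down and recorded
  s1 <- crop_steady_state(erf, skip = 0, length = 1.26)
  expect_equal(dim(s1$data)[3], 50L)
  expect_equal(attr(s1, "actual_length"), 1.25)

  expect_error(crop_steady_state(erf, skip = 5, length = 11.25), "exceeds")
})

test_that("FFT power follows the documented convention (bins, ratios, Parseval)", {
  sf <- 40; dur <- 11.25; n <- sf * dur
  t <- (0:(n - 1)) / sf
  tone <- function(a, f) a * sin(2 * pi * f * t)
  as_erf <- function(x) {
    structure(list(data = array(x, c(1, 1, length(x))), sfreq = sf, t0 = 1.25,
                   condition = "x", n_trials_averaged = 1, side = NULL),
              class = "evoked")
  }
  sp <- power_spectrum(as_erf(tone(1, 0.8)))
  expect_equal(sp$bin_spacing, 1 / 11.25)
  k9 <- which.min(abs(sp$freqs - 0.8))
  expect_equal(k9, 10L)                       # 0.8 Hz is the 9th nonzero bin
  pw <- drop(sp$power)
  expect_equal(pw[k9], 0.25, tolerance = 1e-12)      # |X|^2/T^2 of unit sine
  expect_lt(max(pw[-k9]), 1e-24)

  # amplitudes 1 and 2 at distinct bin centers: power ratio 1:4
  sp2 <- power_spectrum(as_erf(tone(1, 0.8) + tone(2, 1.6)))
  pw2 <- drop(sp2$power)
  expect_equal(pw2[which.min(abs(sp2$freqs - 1.6))] /
                 pw2[which.min(abs(sp2$freqs - 0.8))], 4, tolerance = 1e-9)

  # Parseval: mean square = DC + 2 * interior + Nyquist (even length)
  set.seed(3); x <- rnorm(n)
  pw3 <- drop(power_spectrum(as_erf(x))$power)
  nb <- length(pw3)
  total <- pw3[1] + 2 * sum(pw3[2:(nb - 1)]) + pw3[nb]
  expect_equal(total, mean(x^2), tolerance = 1e-10)
})

test_that("neighbor-bin test statistics behave per definition", {
  freqs <- (0:60) / 11.25
  flat <- matrix(5, nrow = 6, ncol = length(freqs))
  ps <- neighbor_bin_test(flat, freqs)
  expect_true(all(ps$t == 0))
  expect_true(all(ps$p_raw == 0.5))
  expect_true(all(ps$degenerate))

  # scale invariance of t
  set.seed(31)
  pw <- matrix(rexp(10 * length(freqs)), 10)
  a <- neighbor_bin_test(pw, freqs)
  b <- neighbor_bin_test(pw * 37.5, freqs)
  expect_equal(a$t, b$t, tolerance = 1e-12)
  expect_equal(a$p_fdr, b$p_fdr, tolerance = 1e-12)

  # BH step-up arithmetic
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  # df bookkeeping: units - 1
  expect_true(all(neighbor_bin_test(pw[1:5, ], freqs)$df == 4L))
})

test_that("peak power subtracts the flanking average and cancels linear trends", {
  freqs <- c(0.6, 0.8, 1.0)
  expect_equal(peak_power(c(1, 4, 3), freqs, 0.8), 2)
  expect_equal(peak_power(c(2, 2, 2), freqs, 0.8), 0)
  expect_error(peak_power(c(1, 2, 3), freqs, 1.35), "aligned")

  set.seed(32)
  freqs2 <- (0:50) / 11.25
  pw <- matrix(rexp(4 * 51), 4)
  trend <- matrix(rep(3 + 0.7 * freqs2, each = 4), 4)
  expect_equal(peak_power(pw + trend, freqs2, 0.8),
               peak_power(pw, freqs2, 0.8), tolerance = 1e-12)
})

test_that("condition contrast handles identity, shift and degenerate cases", {
  x <- c(3, 5, 4, 6, 2)
  same <- condition_contrast(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_raw, 1)

  y <- x + 1
  up <- condition_contrast(y, x, tails = "one")
  expect_true(up$degenerate)          # constant difference, zero spread
  expect_equal(up$t, Inf)

  z <- x + c(0.5, 1.5, 1, 2, 0.8)
  ct <- condition_contrast(z, x)
  d <- z - x
  expect_equal(ct$cohens_d, mean(d) / sd(d))
  expect_equal(ct$t, mean(d) / (sd(d) / sqrt(5)))

  expect_error(condition_contrast(1:4, 1:5), "pairing")
})

test_that("lateralization test contrasts hemispheres at the target bin", {
  set.seed(33)
  freqs <- (0:50) / 11.25
  k <- which.min(abs(freqs - 4))
  pw <- array(rexp(10 * 6 * 51), c(10, 6, 51))
  side <- factor(c("left", "left", "midline", "right", "right", "right"),
                 levels = c("left", "midline", "right"))
  base <- lateralization_test(pw, 4, side = side, freqs = freqs)

  # doubling right-side power at the bin pushes t positive
  pw2 <- pw
  pw2[, side == "right", k] <- pw2[, side == "right", k] * 2 + 5
  expect_gt(lateralization_test(pw2, 4, side = side, freqs = freqs)$t, base$t)
  expect_gt(lateralization_test(pw2, 4, side = side, freqs = freqs)$t, 0)

  expect_error(lateralization_test(pw[1, , , drop = FALSE], 4, side = side,
                                   freqs = freqs), "2 subjects")
  expect_error(lateralization_test(pw, 4, side = factor(rep("right", 6)),
                                   freqs = freqs), "geometry")
})

test_that("lateralization p values are uniform under a mirror-symmetric null", {
  # symmetric sensor geometry, sources driven identically on both sides:
  # two-tailed p across repeated noise draws should be uniform
  set.seed(34)
  nrun <- 400; nsub <- 8; nch <- 6
  side <- factor(rep(c("left", "right"), each = 3),
                 levels = c("left", "midline", "right"))
  freqs <- (0:20) / 11.25
  k <- which.min(abs(freqs - 0.8))
  pvals <- numeric(nrun)
  for (r in seq_len(nrun)) {
    pw <- array(rexp(nsub * nch * 21), c(nsub, nch, 21))
    pvals[r] <- lateralization_test(pw, 0.8, side = side, freqs = freqs)$p_raw
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("z-scored spectra exclude tagged bins from the background", {
  freqs <- seq(0.5, 4.5, by = 0.5)        # 0.8/4 not on this axis: use custom
  freqs <- c(0.6, 0.7, 0.8, 0.9, 1.0, 1.1, 4.0)
  pw <- c(1, 2, 6, 3, 4, 5, 100)
  z <- zscore_spectrum(pw, freqs, band = c(0.5, 4.5), exclude = c(0.8, 4))
  bg <- c(1, 2, 3, 4, 5)
  expect_equal(z[3], (6 - mean(bg)) / sd(bg), tolerance = 1e-12)
  expect_equal(z[3], 1.897, tolerance = 1e-3)

  # perturbing an excluded bin leaves all other scores unchanged
  pw2 <- pw; pw2[7] <- 1e6
  expect_equal(zscore_spectrum(pw2, freqs)[1:6], z[1:6], tolerance = 1e-12)

  expect_error(zscore_spectrum(rep(3, 7), freqs), "degenerate")
})
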