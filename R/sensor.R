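#' Pre-whiten epochs on the pre-stimulus baseline
#'
#' A diagonal noise covariance is estimated per subject and channel from
#' the pre-stimulus baseline (pooling trials and baseline samples), and
#' every channel is divided by its baseline standard deviation.  After
#' whitening all channels are unitless with baseline variance 1, so
#' heterogeneous channel types can be averaged together.
#'
#' @param epochs a [sensor_epochs()] object with `t0 < 0`.
#' @param baseline_window length-2 window (s) relative to stimulus onset;
#'   default the whole pre-stimulus segment `c(t0, 0)`.
#' @return pre-whitened `sensor_epochs`; the per-subject x channel scale
#'   factors are attached as attribute `"baseline_sd"`.
#' @export
prewhiten <- function(epochs, baseline_window = NULL) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  bw <- baseline_window %||% c(epochs$t0, 0)
  if (bw[1L] < epochs$t0 - 1e-9 || bw[2L] > 1e-9)
    stopf("baseline window must lie within the pre-stimulus segment [%g, 0]",
          epochs$t0)
  sf <- epochs$sfreq
  i0 <- round((bw[1L] - epochs$t0) * sf) + 1L
  i1 <- round((bw[2L] - epochs$t0) * sf)
  if (i1 <= i0) stopf("baseline window too short")
  d <- dim(epochs$data)
  out <- epochs$data
  sds <- matrix(NA_real_, d[1L], d[3L])
  for (s in seq_len(d[1L])) {
    base <- epochs$data[s, , , i0:i1, drop = FALSE]
    for (ch in seq_len(d[3L])) {
      sdc <- sd(as.vector(base[1, , ch, ]))
      if (!is.finite(sdc) || sdc == 0)
        stopf("degenerate channel %d (subject %d): zero baseline variance",
              ch, s)
      sds[s, ch] <- sdc
      out[s, , ch, ] <- out[s, , ch, ] / sdc
    }
  }
  res <- sensor_epochs(out, epochs$sfreq, epochs$t0, epochs$condition,
                       epochs$side)
  attr(res, "baseline_sd") <- sds
  res
}

#' Average trials into the evoked response
#'
#' @param epochs a [sensor_epochs()] object with at least one trial.
#' @return object of class `evoked`: `data` `[subject, channel, time]`,
#'   `sfreq`, `t0`, `condition`, `n_trials_averaged`, `side`.
#' @export
average_erf <- function(epochs) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  d <- dim(epochs$data)
  if (d[2L] < 1L) stopf("empty input: no trials to average")
  ev <- colMeans(aperm(epochs$data, c(2L, 1L, 3L, 4L)))  # mean over trials
  structure(list(data = ev, sfreq = epochs$sfreq, t0 = epochs$t0,
                 condition = epochs$condition, n_trials_averaged = d[2L],
                 side = epochs$side),
            class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<evoked> %d subjects x %d channels x %d samples @ %g Hz (%d trials averaged)\n",
              d[1L], d[2L], d[3L], x$sfreq, x$n_trials_averaged))
  invisible(x)
}

#' Crop the evoked response to its steady-state window
#'
#' Discards the first `skip` seconds after stimulus onset (the transient
#' response) and keeps the next `length` seconds.  Defaults implement the
#' package's standard windowing: skip 1.25 s of a 12.5 s stimulation,
#' keeping 11.25 s and hence a spectral resolution of 1/11.25 ~ 0.089 Hz.
#' A non-integer number of samples is rounded down and the realized window
#' length recorded in attribute `"actual_length"`.
#'
#' @param erf an [average_erf()] object.
#' @param skip seconds to discard after onset.
#' @param length seconds to keep.
#' @return cropped `evoked` (with `t0 = skip`).
#' @export
crop_steady_state <- function(erf, skip = 1.25, length = 11.25) {
  stopifnot(inherits(erf, "evoked"))
  sf <- erf$sfreq
  n_time <- dim(erf$data)[3L]
  onset <- round(-erf$t0 * sf)              # samples before onset
  i0 <- onset + round(skip * sf) + 1L
  nkeep <- floor(length * sf)
  if (i0 < 1L || i0 + nkeep - 1L > n_time)
    stopf("window [%g, %g) s exceeds the available post-onset data", skip,
          skip + length)
  out <- structure(list(data = erf$data[, , i0:(i0 + nkeep - 1L), drop = FALSE],
                        sfreq = sf, t0 = skip, condition = erf$condition,
                        n_trials_averaged = erf$n_trials_averaged,
                        side = erf$side),
                   class = "evoked")
  attr(out, "actual_length") <- nkeep / sf
  out
}

#' Evoked power spectrum
#'
#' Per-channel FFT power of the (pre-whitened, trial-averaged, cropped)
#' evoked response: no taper, no zero padding, power = squared modulus of
#' the DFT coefficient scaled by `1/T^2` (a bin-centered unit sinusoid
#' then carries power 1/4 in its positive-frequency bin).  With this
#' convention the one-sided powers satisfy Parseval's identity:
#' `mean(x^2) = P[DC] + 2 * sum(interior bins) (+ Nyquist bin once)`.
#' The channel-average spectrum, the unit entering group statistics, is
#' attached as `channel_average`.
#'
#' @param erf an `evoked` object (typically from [crop_steady_state()]).
#' @return object of class `spectral_power`: `power` `[subject, channel,
#'   bin]`, `channel_average` `[subject, bin]`, `freqs`, `bin_spacing`.
#' @export
power_spectrum <- function(erf) {
  stopifnot(inherits(erf, "evoked"))
  d <- dim(erf$data)
  n <- d[3L]
  if (n < 2L) stopf("window length must be positive")
  nbin <- floor(n / 2) + 1L
  dur <- n / erf$sfreq
  pw <- array(NA_real_, c(d[1L], d[2L], nbin))
  for (s in seq_len(d[1L])) {
    M <- array(erf$data[s, , , drop = FALSE], dim = d[2:3])  # channels x time
    X <- mvfft(t(M))                                         # time in rows
    pw[s, , ] <- t(Mod(X[seq_len(nbin), , drop = FALSE])^2 / n^2)
  }
  structure(list(power = pw,
                 channel_average = apply(pw, c(1L, 3L), mean),
                 freqs = (seq_len(nbin) - 1L) / dur,
                 bin_spacing = 1 / dur, sfreq = erf$sfreq,
                 condition = erf$condition, side = erf$side,
                 n_samples = n),
            class = "spectral_power")
}

#' @export
print.spectral_power <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<spectral_power> %d subjects x %d channels x %d bins (spacing %.4g Hz)\n",
              d[1L], d[2L], d[3L], x$bin_spacing))
  invisible(x)
}

freq_to_bin <- function(freqs, f, spacing) {
  i <- which.min(abs(freqs - f))
  if (abs(freqs[i] - f) > spacing / 2 + 1e-9)
    stopf("frequency %g Hz is not aligned to a bin center (nearest: %g Hz)",
          f, freqs[i])
  i
}

#' Neighbor-bin spectral peak test
#'
#' For every frequency bin in the band of interest, tests whether the
#' per-unit power at that bin exceeds the average of its two flanking
#' bins, with a one-tailed paired t test across units (subjects at the
#' sensor level, trials at the contact level).  P values are adjusted by
#' Benjamini-Hochberg FDR across all tested bins; Cohen's d is the mean
#' paired difference over the SD of the differences (d_z).
#'
#' Bins whose neighbors fall outside the spectrum are skipped with a
#' warning; a zero-variance difference is reported as `t = Inf, p = 0`
#' (or the mirrored degenerate value) and flagged in the `degenerate`
#' column.
#'
#' @param powers numeric matrix `units x bins` of spectral power (e.g. the
#'   `channel_average` of a [power_spectrum()], or per-trial envelope
#'   spectra).
#' @param freqs bin-center frequencies matching `ncol(powers)`.
#' @param band length-2 band of interest in Hz (default `c(0.5, 4.5)`).
#' @return data frame of class `peak_stats` with columns `freq`, `t`,
#'   `df`, `p_raw`, `p_fdr`, `cohens_d`, `degenerate`.
#' @export
neighbor_bin_test <- function(powers, freqs, band = c(0.5, 4.5)) {
  powers <- as.matrix(powers)
  if (nrow(powers) < 3L) stopf("need at least 3 paired units")
  if (length(freqs) != ncol(powers)) stopf("freqs does not match power bins")
  sel <- which(freqs >= band[1L] - 1e-9 & freqs <= band[2L] + 1e-9)
  edge <- sel[sel <= 1L | sel >= length(freqs)]
  if (length(edge)) {
    warnf("skipping %d bin(s) at the spectrum edge", length(edge))
    sel <- setdiff(sel, edge)
  }
  if (!length(sel)) stopf("no testable bins in band [%g, %g] Hz", band[1L], band[2L])
  rows <- lapply(sel, function(k) {
    dvec <- powers[, k] - (powers[, k - 1L] + powers[, k + 1L]) / 2
    st <- paired_t_stats(dvec, "one")
    data.frame(freq = freqs[k], t = st$t, df = st$df, p_raw = st$p,
               cohens_d = st$d, degenerate = st$degenerate)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p_raw, method = "BH")
  out <- out[, c("freq", "t", "df", "p_raw", "p_fdr", "cohens_d", "degenerate")]
  class(out) <- c("peak_stats", "data.frame")
  out
}

#' @export
print.peak_stats <- function(x, digits = 4, ...) {
  cat("<peak_stats>\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Baseline-corrected peak power at a tagged frequency
#'
#' Power at the target bin minus the average of its two flanking bins;
#' this neighbor-average correction cancels any locally linear spectral
#' trend, isolating the narrow-band tagged response.
#'
#' @param powers per-unit spectra (`units x bins` matrix) or a single
#'   spectrum vector.
#' @param freqs bin-center frequencies.
#' @param f target frequency (Hz); must align with an interior bin center
#'   within half a bin spacing.
#' @return numeric vector of per-unit peak power (scalar for a vector
#'   input).
#' @export
peak_power <- function(powers, freqs, f) {
  vec <- is.null(dim(powers))
  powers <- rbind(powers)
  spacing <- freqs[2L] - freqs[1L]
  k <- freq_to_bin(freqs, f, spacing)
  if (k <= 1L || k >= length(freqs))
    stopf("target bin %g Hz has no interior neighbors", f)
  out <- powers[, k] - (powers[, k - 1L] + powers[, k + 1L]) / 2
  if (vec && length(out) == 1L) unname(out[1L]) else unname(out)
}

#' Paired condition contrast of per-unit scalars
#'
#' Paired t test (one- or two-tailed) of two matched per-unit measurements
#' (e.g. imagery vs baseline peak power), with Cohen's d_z.
#'
#' @param peaks_a,peaks_b equal-length per-unit vectors, paired by unit.
#' @param tails `"two"` (default) or `"one"` (tests `a > b`).
#' @return one-row `peak_stats` data frame (`freq` is `NA`).
#' @export
condition_contrast <- function(peaks_a, peaks_b, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(peaks_a) != length(peaks_b))
    stopf("pairing error: %d vs %d units", length(peaks_a), length(peaks_b))
  st <- paired_t_stats(peaks_a - peaks_b, tails)
  out <- data.frame(freq = NA_real_, t = st$t, df = st$df, p_raw = st$p,
                    p_fdr = st$p, cohens_d = st$d, degenerate = st$degenerate)
  class(out) <- c("peak_stats", "data.frame")
  out
}

#' Hemispheric lateralization test at a tagged frequency
#'
#' Per unit (subject), power at the target bin is averaged over left-side
#' and right-side sensors separately (midline sensors excluded), and a
#' two-tailed paired t test across units evaluates the right minus left
#' difference.
#'
#' @param sp a [power_spectrum()] object carrying per-channel power and a
#'   channel `side` factor, or a 3-D array `[subject, channel, bin]` plus
#'   explicit `side`/`freqs` arguments.
#' @param f target frequency (Hz).
#' @param side optional per-channel factor with levels left/midline/right.
#' @param freqs optional bin centers when `sp` is a bare array.
#' @return one-row `peak_stats` data frame; the per-unit right and left
#'   means are attached as attribute `"side_means"`.
#' @export
lateralization_test <- function(sp, f, side = NULL, freqs = NULL) {
  if (inherits(sp, "spectral_power")) {
    pw <- sp$power
    side <- side %||% sp$side
    freqs <- freqs %||% sp$freqs
  } else pw <- sp
  if (is.null(side)) stopf("sensor sides are required")
  side <- as.character(side)
  li <- which(side == "left")
  ri <- which(side == "right")
  if (!length(li) || !length(ri))
    stopf("geometry error: need sensors on both sides (left: %d, right: %d)",
          length(li), length(ri))
  k <- freq_to_bin(freqs, f, freqs[2L] - freqs[1L])
  lmean <- apply(pw[, li, k, drop = FALSE], 1L, mean)
  rmean <- apply(pw[, ri, k, drop = FALSE], 1L, mean)
  if (length(lmean) < 2L) stopf("need at least 2 subjects (df >= 1)")
  st <- paired_t_stats(rmean - lmean, "two")
  out <- data.frame(freq = f, t = st$t, df = st$df, p_raw = st$p,
                    p_fdr = st$p, cohens_d = st$d, degenerate = st$degenerate)
  class(out) <- c("peak_stats", "data.frame")
  attr(out, "side_means") <- cbind(left = lmean, right = rmean)
  out
}

#' Z-score a spectrum against its non-tagged background
#'
#' For display, each bin is expressed as a Z score against the background
#' bins of the band of interest, excluding the tagged frequencies: `z(f) =
#' (P(f) - mean_bg) / sd_bg`, where the background is every bin with
#' center in `band` whose frequency is not within half a bin of an entry
#' of `exclude`.
#'
#' @param powers spectrum vector or `units x bins` matrix.
#' @param freqs bin-center frequencies.
#' @param band background band (default `c(0.5, 4.5)` Hz).
#' @param exclude tagged frequencies excluded from the background
#'   (default `c(0.8, 4)` Hz, with their spacing-wide neighborhoods).
#' @return z-scores, same shape as `powers`.
#' @export
zscore_spectrum <- function(powers, freqs, band = c(0.5, 4.5),
                            exclude = c(0.8, 4)) {
  vec <- is.null(dim(powers))
  powers <- rbind(powers)
  spacing <- freqs[2L] - freqs[1L]
  bg <- freqs >= band[1L] - 1e-9 & freqs <= band[2L] + 1e-9
  for (f in exclude) bg <- bg & abs(freqs - f) > spacing / 2 - 1e-9
  if (sum(bg) < 3L) stopf("need at least 3 background bins")
  out <- powers
  for (u in seq_len(nrow(powers))) {
    mu <- mean(powers[u, bg])
    sdv <- sd(powers[u, bg])
    if (sdv == 0) stopf("degenerate spectrum: zero background SD (unit %d)", u)
    out[u, ] <- (powers[u, ] - mu) / sdv
  }
  if (vec) drop(out) else out
}

#' Zero-phase FIR pre-filtering of epochs
#'
#' Applies the standard broadband bandpass (default 0.2-60 Hz) and an
#' optional notch to every trial, with reflection padding against edge
#' effects.  Corners above what the sampling rate supports are clipped
#' with a warning.
#'
#' @param epochs a [sensor_epochs()] object.
#' @param low,high bandpass corners (Hz).
#' @param notch optional notch center (Hz), e.g. 50 for line noise;
#'   `NULL` disables.  Ignored (with a warning) when above the usable
#'   range.
#' @return filtered `sensor_epochs`.
#' @export
prefilter_epochs <- function(epochs, low = 0.2, high = 60, notch = NULL) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  sf <- epochs$sfreq
  hmax <- 0.45 * sf
  if (high > hmax) {
    warnf("clipping upper corner from %g to %g Hz (sampling rate %g Hz)",
          high, hmax, sf)
    high <- hmax
  }
  d <- dim(epochs$data)
  out <- epochs$data
  for (s in seq_len(d[1L])) for (tr in seq_len(d[2L])) {
    x <- t(matrix(epochs$data[s, tr, , ], d[3L], d[4L]))
    y <- fir_bandpass(x, sf, low, high)
    if (!is.null(notch)) {
      if (notch < hmax) {
        lownotch <- fir_bandpass(y, sf, notch - 2, notch + 2)
        y <- y - lownotch
      } else warnf("notch %g Hz above usable range; skipped", notch)
    }
    out[s, tr, , ] <- t(y)
  }
  sensor_epochs(out, sf, epochs$t0, epochs$condition, epochs$side)
}
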