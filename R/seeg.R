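#' High-gamma amplitude envelope of a contact
#'
#' The high-gamma band (default 60-100 Hz), a proxy for local population
#' firing, is isolated by a zero-phase FIR bandpass per trial and the
#' instantaneous amplitude envelope extracted as the magnitude of the
#' analytic signal (Hilbert transform).  One filter length of samples at
#' each end is flagged as edge-contaminated (attribute `"n_edge"`) and
#' should be excluded from spectral windows.
#'
#' @param record a [simulate_seeg()] style `contact_record`.
#' @param band length-2 bandpass (Hz), default `c(60, 100)`.
#' @return trials x time matrix of envelopes with attributes `n_edge`,
#'   `sfreq`, `t0`.
#' @export
highgamma_envelope <- function(record, band = c(60, 100)) {
  stopifnot(inherits(record, "contact_record"))
  sf <- record$sfreq
  if (band[2L] >= sf / 2)
    stopf("band edge %.3g Hz is at or above Nyquist (%.3g Hz)", band[2L], sf / 2)
  x <- t(record$trace)                       # time x trials
  filt <- fir_bandpass(x, sf, band[1L], band[2L])
  env <- Mod(analytic_signal(filt))
  out <- t(env)
  attr(out, "n_edge") <- attr(filt, "taps")
  attr(out, "sfreq") <- sf
  attr(out, "t0") <- record$t0
  out
}

#' Per-trial envelope power spectra
#'
#' Crops each trial's envelope to the steady-state window (default: skip
#' the first 1.25 s after stimulus onset, keep 11.25 s, mirroring the
#' sensor-level convention) and computes the per-trial FFT power spectrum
#' with the same scaling as [power_spectrum()].
#'
#' @param env envelope matrix from [highgamma_envelope()] (carrying
#'   `sfreq`/`t0` attributes), or any trials x time matrix with `sfreq`
#'   and `t0` supplied.
#' @param skip,window_length steady-state window (s) after onset.
#' @param sfreq,t0 sampling rate and epoch start; default from attributes.
#' @return object of class `envelope_spectrum`: `power` (trials x bins),
#'   `freqs`, `bin_spacing`.
#' @export
envelope_spectrum <- function(env, skip = 1.25, window_length = 11.25,
                              sfreq = NULL, t0 = NULL) {
  sfreq <- sfreq %||% attr(env, "sfreq")
  t0 <- t0 %||% attr(env, "t0")
  if (is.null(sfreq) || is.null(t0)) stopf("sfreq and t0 are required")
  n <- ncol(env)
  onset <- round(-t0 * sfreq)
  i0 <- onset + round(skip * sfreq) + 1L
  nkeep <- floor(window_length * sfreq)
  if (i0 < 1L || i0 + nkeep - 1L > n)
    stopf("window [%g, %g) s exceeds the trial", skip, skip + window_length)
  seg <- env[, i0:(i0 + nkeep - 1L), drop = FALSE]
  X <- mvfft(t(seg))
  nbin <- floor(nkeep / 2) + 1L
  power <- t(Mod(X[seq_len(nbin), , drop = FALSE])^2 / nkeep^2)
  structure(list(power = power, freqs = (seq_len(nbin) - 1L) / (nkeep / sfreq),
                 bin_spacing = sfreq / nkeep),
            class = "envelope_spectrum")
}

#' @export
print.envelope_spectrum <- function(x, ...) {
  cat(sprintf("<envelope_spectrum> %d trials x %d bins (spacing %.4g Hz)\n",
              nrow(x$power), ncol(x$power), x$bin_spacing))
  invisible(x)
}

#' Per-contact neighbor-bin peak test across trials
#'
#' The contact-level analogue of the sensor [neighbor_bin_test()]: for
#' every envelope-spectrum bin in the band of interest, a one-tailed
#' paired t test across trials of bin power against the mean of the two
#' flanking bins, FDR corrected across bins.  The paired unit is the
#' trial, so `df = trials - 1`.
#'
#' @param spec an [envelope_spectrum()].
#' @param band band of interest (Hz), default `c(0.5, 4.5)`.
#' @param trial_mask optional logical vector of trials to keep (e.g. the
#'   correct-report mask of the paradigm).
#' @return `peak_stats` data frame as in [neighbor_bin_test()].
#' @export
contact_peak_test <- function(spec, band = c(0.5, 4.5), trial_mask = NULL) {
  stopifnot(inherits(spec, "envelope_spectrum"))
  pw <- spec$power
  if (!is.null(trial_mask)) pw <- pw[trial_mask, , drop = FALSE]
  neighbor_bin_test(pw, spec$freqs, band)
}

#' Normalized spectral peak (bounded tagging-strength index)
#'
#' `(P_target - P_neighboring) / (P_target + P_neighboring)` where
#' `P_neighboring` is the average power of the two bins flanking the
#' target bin.  The index is bounded in `[-1, 1]`, equals 0 for a flat
#' spectrum and 1 when the neighbors carry no power, and is invariant to
#' rescaling both powers by any positive constant.
#'
#' @param p_target nonnegative target-bin power (vectorized).
#' @param p_neighboring nonnegative averaged flanking power.
#' @return normalized peak value(s) in `[-1, 1]`.
#' @export
normalized_peak <- function(p_target, p_neighboring) {
  if (any(p_target < 0) || any(p_neighboring < 0))
    stopf("powers must be nonnegative")
  tot <- p_target + p_neighboring
  if (any(tot == 0)) stopf("undefined peak: target and neighboring power both zero")
  (p_target - p_neighboring) / tot
}

#' Per-trial normalized peaks at a target frequency
#'
#' @param spec an [envelope_spectrum()].
#' @param f target frequency (Hz), an interior bin center.
#' @param trial_mask optional logical trial filter.
#' @return numeric vector, one normalized peak per trial.
#' @export
trial_normalized_peaks <- function(spec, f, trial_mask = NULL) {
  stopifnot(inherits(spec, "envelope_spectrum"))
  pw <- spec$power
  if (!is.null(trial_mask)) pw <- pw[trial_mask, , drop = FALSE]
  k <- freq_to_bin(spec$freqs, f, spec$bin_spacing)
  if (k <= 1L || k >= length(spec$freqs)) stopf("target bin has no neighbors")
  normalized_peak(pw[, k], (pw[, k - 1L] + pw[, k + 1L]) / 2)
}

#' Pooled normalized-peak statistics per region and condition
#'
#' Trials from same-region contacts are pooled.  Per region and
#' condition, a one-tailed one-sample t test evaluates whether the
#' normalized peak exceeds zero (df = pooled trials - 1).  Per region, a
#' two-tailed independent t test with pooled variance (df = n1 + n2 - 2)
#' contrasts the two conditions.  Cohen's d is mean/SD for the one-sample
#' test and the pooled-SD standardized mean difference for the contrast.
#'
#' @param peaks data frame with columns `value` (normalized peak per
#'   trial), `region`, `condition` (and optionally `contact`).
#' @return list with data frames `one_sample` (region, condition, n, df,
#'   t, p, cohens_d) and `contrast` (region, n_a, n_b, df, t, p,
#'   cohens_d), of class `region_stats`.
#' @export
region_pool_test <- function(peaks) {
  stopifnot(is.data.frame(peaks), all(c("value", "region", "condition") %in%
                                        names(peaks)))
  regions <- unique(peaks$region)
  one <- list(); con <- list()
  for (r in regions) {
    sub <- peaks[peaks$region == r, ]
    conds <- unique(sub$condition)
    for (cc in conds) {
      v <- sub$value[sub$condition == cc]
      if (length(v) < 2L) stopf("singleton group: region %s, condition %s", r, cc)
      st <- paired_t_stats(v, "one")          # one-sample vs 0, one-tailed
      one[[length(one) + 1L]] <-
        data.frame(region = r, condition = cc, n = length(v), df = st$df,
                   t = st$t, p = st$p, cohens_d = st$d)
    }
    if (length(conds) == 2L) {
      va <- sub$value[sub$condition == conds[1L]]
      vb <- sub$value[sub$condition == conds[2L]]
      n1 <- length(va); n2 <- length(vb)
      sp2 <- ((n1 - 1L) * stats::var(va) + (n2 - 1L) * stats::var(vb)) /
        (n1 + n2 - 2L)
      if (sp2 == 0) {
        tval <- if (mean(va) == mean(vb)) 0 else sign(mean(va) - mean(vb)) * Inf
        p <- if (tval == 0) 1 else 0
        d <- if (tval == 0) 0 else tval
      } else {
        tval <- (mean(va) - mean(vb)) / sqrt(sp2 * (1 / n1 + 1 / n2))
        p <- 2 * pt(-abs(tval), n1 + n2 - 2L)
        d <- (mean(va) - mean(vb)) / sqrt(sp2)
      }
      con[[length(con) + 1L]] <-
        data.frame(region = r, condition_a = conds[1L], condition_b = conds[2L],
                   n_a = n1, n_b = n2, df = n1 + n2 - 2L, t = tval, p = p,
                   cohens_d = d)
    }
  }
  structure(list(one_sample = do.call(rbind, one),
                 contrast = if (length(con)) do.call(rbind, con) else NULL),
            class = "region_stats")
}

#' @export
print.region_stats <- function(x, digits = 4, ...) {
  cat("<region_stats> one-sample normalized-peak tests:\n")
  print.data.frame(x$one_sample, digits = digits, row.names = FALSE)
  if (!is.null(x$contrast)) {
    cat("between-condition contrasts (pooled variance):\n")
    print.data.frame(x$contrast, digits = digits, row.names = FALSE)
  }
  invisible(x)
}
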