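#' Simulation configuration
#'
#' Collects the parameters of the frequency-tagging paradigm that the
#' synthetic MEG generator emulates: a 4 Hz tone train lasting 12.5 s (50
#' tones at 250 ms onset-to-onset intervals) that is mentally grouped at
#' 0.8 Hz (five tones per group, 1.25 s per group), with a 0.5 s
#' pre-stimulus baseline, 15 trials per condition and 20 subjects.
#'
#' Source lists are given as data frames with columns `index` (grid
#' point), `amplitude` and `waveform` (one of `"ramp"`, `"pulse"`,
#' `"sine"`).  The imagery waveform ramps up within each 1.25 s cycle
#' (energy at 0.8 Hz and its harmonics); the stimulus waveform is a train
#' of 100 ms raised-cosine pulses at 4 Hz.
#'
#' @param seed integer seed.
#' @param n_subjects,n_trials subjects and trials per condition.
#' @param sfreq sampling rate (Hz); must exceed `2 * f_stim`.
#' @param t_pre,t_stim baseline and stimulation lengths (s); `t_stim` must
#'   be an integer multiple of `1 / f_img`.
#' @param f_img,f_stim imagery-rate and stimulus-rate frequencies (Hz);
#'   `f_stim` must be an integer multiple of `f_img`.
#' @param imagery_sources,stimulus_sources source data frames (see above);
#'   `NULL` picks defaults from the leadfield grid at simulation time (one
#'   central imagery source, two lateral stimulus sources).
#' @param noise_sd channel noise standard deviation, in the same units as
#'   gain x amplitude.
#' @param noise_color `"pink"` (default, realistic 1/f background) or
#'   `"white"`.
#' @param subject_amp_sd log-normal sd of per-subject source amplitude
#'   scaling (between-subject variability).
#' @param phase_jitter sd (s) of a per-trial onset jitter of the imagery
#'   rhythm; 0 (default) means perfectly locked imagery.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_subjects = 20L, n_trials = 15L,
                       sfreq = 100, t_pre = 0.5, t_stim = 12.5,
                       f_img = 0.8, f_stim = 4,
                       imagery_sources = NULL, stimulus_sources = NULL,
                       noise_sd = 1, noise_color = c("pink", "white"),
                       subject_amp_sd = 0.2, phase_jitter = 0) {
  noise_color <- match.arg(noise_color)
  if (f_img <= 0 || f_stim <= 0) stopf("frequencies must be positive")
  ratio <- f_stim / f_img
  if (abs(ratio - round(ratio)) > 1e-9)
    stopf("f_stim (%g) must be an integer multiple of f_img (%g)", f_stim, f_img)
  ncyc <- t_stim * f_img
  if (abs(ncyc - round(ncyc)) > 1e-9)
    stopf("t_stim (%g s) must be an integer multiple of 1/f_img (%g s)",
          t_stim, 1 / f_img)
  if (sfreq <= 2 * f_stim) stopf("sfreq must exceed 2 * f_stim")
  if (n_subjects < 1L || n_trials < 1L) stopf("need >= 1 subject and trial")
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials), sfreq = sfreq,
                 t_pre = t_pre, t_stim = t_stim, f_img = f_img,
                 f_stim = f_stim, imagery_sources = imagery_sources,
                 stimulus_sources = stimulus_sources, noise_sd = noise_sd,
                 noise_color = noise_color, subject_amp_sd = subject_amp_sd,
                 phase_jitter = phase_jitter),
            class = "sim_config")
}

## periodic source waveforms, defined for t >= 0 (stimulus period)
source_waveform <- function(type, t, freq) {
  ph <- (t * freq) %% 1
  switch(type,
    ramp = ph^2,                                  # within-cycle ramp, rich harmonics
    pulse = {                                     # 100 ms raised-cosine pulse train
      w <- 0.1 * freq                             # pulse width as cycle fraction
      ifelse(ph < w, 0.5 * (1 - cos(2 * pi * ph / w)), 0)
    },
    sine = sin(2 * pi * freq * t),
    stopf("unknown waveform type '%s'", type))
}

default_sources <- function(grid, role = c("imagery", "stimulus"), amplitude) {
  role <- match.arg(role)
  pos <- grid$positions
  if (role == "imagery") {
    i <- which.min(rowSums(pos^2))                 # central source
    data.frame(index = i, amplitude = amplitude, waveform = "ramp",
               stringsAsFactors = FALSE)
  } else {
    xr <- range(pos[, 1L])
    target_l <- c(xr[1L], 0, 0)
    target_r <- c(xr[2L], 0, 0)
    il <- which.min(colSums((t(pos) - target_l)^2))
    ir <- which.min(colSums((t(pos) - target_r)^2))
    data.frame(index = c(il, ir), amplitude = amplitude, waveform = "pulse",
               stringsAsFactors = FALSE)
  }
}

#' Simulate frequency-tagged MEG-like sensor epochs
#'
#' Sensor data are `leadfield x source currents + channel noise`, trial
#' structured with a silent pre-stimulus baseline.  Under the imagery
#' condition both the slow (imagery-rate, 0.8 Hz) and the fast
#' (stimulus-rate, 4 Hz) sources are active; under the baseline condition
#' only the stimulus-rate sources are active.  Each active source is given
#' a fixed random orientation (seeded), and each subject a log-normal
#' amplitude scaling.  Ground-truth source time courses are returned for
#' recovery tests.
#'
#' @param config a [sim_config()].
#' @param lf a [make_leadfield()] leadfield; its grid defines valid source
#'   indices.
#' @param conditions which conditions to generate (default both).
#' @return list with `imagery` and/or `baseline` (class `sensor_epochs`)
#'   and `truth` (source tables, orientations, time courses, subject
#'   scales).
#' @export
simulate_meg <- function(config, lf,
                         conditions = c("imagery", "baseline")) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  stopifnot(inherits(config, "sim_config"), inherits(lf, "leadfield"))
  grid <- lf$grid
  imagery <- config$imagery_sources %||%
    default_sources(grid, "imagery", amplitude = 1)
  stimulus <- config$stimulus_sources %||%
    default_sources(grid, "stimulus", amplitude = 1)
  for (src in list(imagery, stimulus)) {
    if (any(src$index < 1L | src$index > n_sources(grid)))
      stopf("source index out of range (grid has %d points)", n_sources(grid))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  sf <- config$sfreq
  n_pre <- round(config$t_pre * sf)
  n_stim <- round(config$t_stim * sf)
  n_time <- n_pre + n_stim
  t_stim_axis <- (seq_len(n_stim) - 1L) / sf
  m <- nrow(lf$gain)
  ns <- config$n_subjects
  nt <- config$n_trials

  tag_role <- function(df, role, freq) {
    df$role <- rep(role, nrow(df))
    df$freq <- rep(freq, nrow(df))
    df
  }
  src_all <- rbind(tag_role(imagery, "imagery", config$f_img),
                   tag_role(stimulus, "stimulus", config$f_stim))
  if (!nrow(src_all)) stopf("no sources to simulate")
  # fixed random unit orientation per source, derived from (seed, grid
  # index) so that adding or removing other sources never changes it
  # (keeps the forward model exactly superposable across source sets)
  ori <- t(vapply(src_all$index, function(idx) {
    set.seed((config$seed %% 100000L) * 1009L + idx)
    v <- rnorm(3L)
    v / sqrt(sum(v^2))
  }, numeric(3L)))
  set.seed(config$seed + 1L)      # stream for subject scales, noise, jitter
  # sensor topography of each source: gain block x orientation
  topo <- vapply(seq_len(nrow(src_all)), function(k) {
    drop(source_block(lf, src_all$index[k]) %*% ori[k, ])
  }, numeric(m))                                   # m x n_src
  wave <- vapply(seq_len(nrow(src_all)), function(k) {
    src_all$amplitude[k] *
      source_waveform(src_all$waveform[k], t_stim_axis, src_all$freq[k])
  }, numeric(n_stim))                              # n_stim x n_src

  subj_scale <- exp(rnorm(ns, -config$subject_amp_sd^2 / 2,
                          config$subject_amp_sd))

  make_cond <- function(active, label) {
    data <- array(0, c(ns, nt, m, n_time))
    for (s in seq_len(ns)) {
      for (tr in seq_len(nt)) {
        sig <- matrix(0, m, n_stim)
        for (k in which(active)) {
          wk <- wave[, k]
          if (config$phase_jitter > 0 && src_all$role[k] == "imagery") {
            shift <- rnorm(1L, 0, config$phase_jitter)
            tj <- t_stim_axis - shift
            wk <- src_all$amplitude[k] *
              source_waveform(src_all$waveform[k], pmax(tj, 0), src_all$freq[k])
            wk[tj < 0] <- 0
          }
          sig <- sig + subj_scale[s] * tcrossprod(topo[, k], wk)
        }
        noise <- if (config$noise_sd > 0) {
          nz <- if (config$noise_color == "pink") pink_noise(n_time, m)
                else matrix(rnorm(n_time * m), n_time, m)
          config$noise_sd * t(nz)
        } else matrix(0, m, n_time)
        data[s, tr, , ] <- noise
        data[s, tr, , (n_pre + 1L):n_time] <-
          data[s, tr, , (n_pre + 1L):n_time] + sig
      }
    }
    sensor_epochs(data, sfreq = sf, t0 = -config$t_pre, condition = label,
                  side = lf$side)
  }

  out <- list(imagery = NULL, baseline = NULL)
  if ("imagery" %in% conditions)
    out$imagery <- make_cond(rep(TRUE, nrow(src_all)), "imagery")
  if ("baseline" %in% conditions)
    out$baseline <- make_cond(src_all$role == "stimulus", "baseline")
  out$truth <- list(sources = src_all, orientations = ori,
                    waveforms = wave, time = t_stim_axis,
                    subject_scale = subj_scale)
  out
}

#' Trial-structured multichannel sensor epochs
#'
#' @param data 4-D numeric array `[subject, trial, channel, time]`.
#' @param sfreq sampling rate (Hz).
#' @param t0 epoch start time relative to stimulus onset (s, negative for
#'   a pre-stimulus baseline).
#' @param condition condition label.
#' @param side optional per-channel hemisphere factor
#'   (left/midline/right).
#' @return object of class `sensor_epochs`.
#' @export
sensor_epochs <- function(data, sfreq, t0, condition = "unknown", side = NULL) {
  stopifnot(length(dim(data)) == 4L)
  if (anyNA(data)) stopf("epochs contain NA")
  structure(list(data = data, sfreq = sfreq, t0 = t0, condition = condition,
                 side = side),
            class = "sensor_epochs")
}

#' @export
print.sensor_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("<sensor_epochs> %d subjects x %d trials x %d channels",
                     " x %d samples @ %g Hz (t0 = %g s, condition: %s)\n"),
              d[1L], d[2L], d[3L], d[4L], x$sfreq, x$t0, x$condition))
  invisible(x)
}

#' Simulate an amplitude-modulated intracranial contact
#'
#' Emulates high-gamma tagging at a depth-electrode contact: a band-limited
#' Gaussian carrier in the given band whose instantaneous amplitude during
#' stimulation is `1 + sum(depth_j * cos(2 pi f_j (t - onset)))`, plus
#' optional pink noise.  The carrier is synthesized in the frequency domain
#' (exactly band-limited), so with no noise and zero modulation depth its
#' Hilbert envelope is constant up to narrow-band amplitude fluctuations.
#'
#' @param carrier_band length-2 band (Hz), default `c(60, 100)`.
#' @param carrier `"noise"` (default): band-limited Gaussian noise, whose
#'   envelope carries Rayleigh fluctuations as real high-gamma activity
#'   does; `"tone"`: a deterministic sinusoid at the band center with a
#'   random phase per trial, whose noiseless envelope is exactly the
#'   modulator (useful for envelope-recovery checks).
#' @param mod_freqs list of `c(freq_hz, depth)` pairs, depths in `[0, 1]`.
#' @param n_trials number of trials (>= 2).
#' @param sfreq sampling rate (Hz), >= 256 so the 60-100 Hz band exists.
#' @param seed integer seed.
#' @param t_pre,t_stim baseline and stimulation lengths (s).
#' @param noise_sd pink-noise sd relative to carrier RMS 1.
#' @param region,subject_id,condition,mni metadata carried on the record.
#' @return object of class `contact_record`: `trace` (trials x time),
#'   `sfreq`, `t0`, metadata, and a logical `trial_mask` (all `TRUE`).
#' @export
simulate_seeg <- function(carrier_band = c(60, 100), mod_freqs = list(c(0.8, 0.5)),
                          n_trials = 20L, sfreq = 512, seed = 1L,
                          t_pre = 0.5, t_stim = 12.5, noise_sd = 0.2,
                          carrier = c("noise", "tone"),
                          region = "STG", subject_id = "S1",
                          condition = "imagery", mni = c(0, 0, 0)) {
  carrier <- match.arg(carrier)
  if (carrier_band[2L] >= sfreq / 2)
    stopf("carrier band edge %.3g Hz is at or above Nyquist (%.3g Hz)",
          carrier_band[2L], sfreq / 2)
  if (carrier_band[1L] <= 0 || carrier_band[1L] >= carrier_band[2L])
    stopf("need 0 < low < high carrier band")
  if (sfreq < 256) stopf("sfreq must be >= 256 Hz to support the 60-100 Hz band")
  if (n_trials < 2L) stopf("need >= 2 trials")
  depths <- vapply(mod_freqs, `[`, numeric(1L), 2L)
  if (any(depths < 0 | depths > 1)) stopf("modulation depths must be in [0, 1]")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_pre <- round(t_pre * sfreq)
  n_stim <- round(t_stim * sfreq)
  n <- n_pre + n_stim
  t_rel <- ((seq_len(n) - 1L) - n_pre) / sfreq     # time relative to onset
  env <- rep(1, n)
  post <- t_rel >= 0
  for (mf in mod_freqs) env[post] <- env[post] + mf[2L] * cos(2 * pi * mf[1L] * t_rel[post])

  freqs <- (seq_len(n) - 1L) / n * sfreq
  inband <- (freqs >= carrier_band[1L] & freqs <= carrier_band[2L])
  t_abs <- (seq_len(n) - 1L) / sfreq
  trace <- matrix(0, n_trials, n)
  for (tr in seq_len(n_trials)) {
    carr <- if (carrier == "noise") {
      X <- complex(real = rnorm(n), imaginary = rnorm(n))
      X[!inband] <- 0
      cw <- Re(fft(X, inverse = TRUE)) / n         # band-limited Gaussian noise
      cw / sd(cw)
    } else {
      sin(2 * pi * mean(carrier_band) * t_abs + stats::runif(1L, 0, 2 * pi))
    }
    x <- carr * env
    if (noise_sd > 0) x <- x + noise_sd * drop(pink_noise(n, 1L))
    trace[tr, ] <- x
  }
  structure(list(trace = trace, sfreq = sfreq, t0 = -t_pre, region = region,
                 mni = mni, subject_id = subject_id, condition = condition,
                 trial_mask = rep(TRUE, n_trials),
                 carrier_band = carrier_band, carrier = carrier,
                 mod_freqs = mod_freqs,
                 seed = as.integer(seed)),
            class = "contact_record")
}

#' @export
print.contact_record <- function(x, ...) {
  cat(sprintf("<contact_record> %d trials x %d samples @ %g Hz (%s, %s, %s)\n",
              nrow(x$trace), ncol(x$trace), x$sfreq, x$subject_id, x$region,
              x$condition))
  invisible(x)
}
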