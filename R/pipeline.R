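#' Analysis run configuration
#'
#' Aggregates the constants of the frequency-tagging analysis: the
#' imagery-rate and stimulus-rate frequencies (0.8 and 4 Hz), the band of
#' interest for peak statistics (0.5-4.5 Hz), the steady-state window
#' (skip 1.25 s, keep 11.25 s), the high-gamma band (60-100 Hz), the
#' depth-weighting exponent and the cluster-test thresholds.  Use
#' [validate_config()] (called automatically) to check the invariants,
#' most importantly that the tagged frequencies align with bin centers of
#' the analysis window (with an 11.25 s window, 0.8 Hz is bin 9 and 4 Hz
#' bin 45 of the 1/11.25 ~ 0.089 Hz axis).
#'
#' @param f_img,f_stim tagged frequencies (Hz).
#' @param band band of interest for peak tests (Hz).
#' @param skip,window_length steady-state window (s).
#' @param gamma_band high-gamma band (Hz).
#' @param depth_gamma depth-weighting exponent.
#' @param voxel_alpha,cluster_alpha,n_perm cluster-test parameters.
#' @param fwhm source smoothing kernel FWHM (mm).
#' @param seed integer master seed.
#' @param sim a [sim_config()] for the synthetic stage (defaults match the
#'   paradigm: 20 subjects, 15 trials, 0.5 s baseline, 12.5 s
#'   stimulation).
#' @return validated list of class `run_config` with a provenance `hash`.
#' @export
freqtag_config <- function(f_img = 0.8, f_stim = 4, band = c(0.5, 4.5),
                           skip = 1.25, window_length = 11.25,
                           gamma_band = c(60, 100), depth_gamma = 1,
                           voxel_alpha = 0.001, cluster_alpha = 0.01,
                           n_perm = 1024L, fwhm = 5, seed = 1L, sim = NULL) {
  cfg <- list(f_img = f_img, f_stim = f_stim, band = band, skip = skip,
              window_length = window_length, gamma_band = gamma_band,
              depth_gamma = depth_gamma, voxel_alpha = voxel_alpha,
              cluster_alpha = cluster_alpha, n_perm = as.integer(n_perm),
              fwhm = fwhm, seed = as.integer(seed),
              sim = sim %||% sim_config(seed = seed, f_img = f_img,
                                        f_stim = f_stim))
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' Checks every invariant with an explicit message: positive frequencies,
#' tagged frequencies aligned to bin centers of the analysis window,
#' sensible bands and alphas.  Returns the config (classed, with defaults
#' injected and a provenance hash) or fails.
#'
#' @param cfg a named list as produced by [freqtag_config()].
#' @return validated `run_config`.
#' @export
validate_config <- function(cfg) {
  if (cfg$f_img <= 0 || cfg$f_stim <= 0) stopf("frequencies must be positive")
  for (f in c(img = cfg$f_img, stim = cfg$f_stim)) {
    bins <- f * cfg$window_length
    if (abs(bins - round(bins)) > 1e-6)
      stopf("frequency %g Hz is not a bin center of the %g s window (bin %g)",
            f, cfg$window_length, bins)
  }
  if (cfg$band[1L] >= cfg$band[2L]) stopf("band of interest must be increasing")
  if (cfg$skip < 0 || cfg$window_length <= 0) stopf("invalid analysis window")
  if (cfg$voxel_alpha <= 0 || cfg$voxel_alpha >= 1 ||
      cfg$cluster_alpha <= 0 || cfg$cluster_alpha >= 1)
    stopf("alphas must be in (0, 1)")
  if (cfg$gamma_band[1L] <= 0 || cfg$gamma_band[1L] >= cfg$gamma_band[2L])
    stopf("invalid high-gamma band")
  if (!inherits(cfg$sim, "sim_config")) stopf("sim must be a sim_config")
  if (cfg$sim$t_stim - cfg$skip < cfg$window_length - 1e-9)
    stopf("steady-state window exceeds stimulation length")
  cfg$hash <- object_hash(cfg[setdiff(names(cfg), "hash")])
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> f_img %g Hz, f_stim %g Hz, window %g s (skip %g s), seed %d, hash %s\n",
              x$f_img, x$f_stim, x$window_length, x$skip, x$seed, x$hash))
  invisible(x)
}

## sensor stage: epochs -> channel-average spectra + peak stats
sensor_stage <- function(epochs, cfg) {
  white <- prewhiten(epochs)
  erf <- average_erf(white)
  sp <- power_spectrum(crop_steady_state(erf, cfg$skip, cfg$window_length))
  list(spectrum = sp,
       peak_stats = neighbor_bin_test(sp$channel_average, sp$freqs, cfg$band))
}

## source stage: per-subject complex bins -> per-subject maps at the
## target bin and its neighbor-average control, smoothed and logged.
## Solves use the noise-aware epsilon-cone with the noise scale estimated
## per subject from the off-peak bins (see estimate_noise_tol).
source_stage_maps <- function(white_epochs, rlf, w, cfg, f) {
  erf <- average_erf(white_epochs)
  ss <- crop_steady_state(erf, cfg$skip, cfg$window_length)
  d <- dim(ss$data)
  n <- d[3L]
  dur <- n / ss$sfreq
  kt <- round(f * dur) + 1L
  freqs <- (seq_len(n) - 1L) / dur
  nsubj <- d[1L]
  tgt <- vector("list", nsubj); ctl <- vector("list", nsubj)
  n_zero_maps <- 0L   # noise-only bins below the eps-cone give empty maps
  for (s in seq_len(nsubj)) {
    M <- array(ss$data[s, , , drop = FALSE], dim = d[2:3])
    X <- mvfft(t(M)) / n                 # complex spectrum, time in rows
    eps <- estimate_noise_tol(X, freqs, cfg$band,
                              c(cfg$f_img, cfg$f_stim))
    maps <- lapply(c(kt - 1L, kt, kt + 1L), function(k) {
      fit <- solve_l1_bin(X[k, ], rlf, weights = w, noise_tol = eps,
                          freq = (k - 1L) / dur,
                          max_iter = 20000L, tol_rel = 1e-5, tol_abs = 1e-9)
      rms_activation(fit)
    })
    quiet_log <- function(mp) {
      withCallingHandlers(smooth_and_log(mp, cfg$fwhm),
        warning = function(wn) {
          if (grepl("all-zero map", conditionMessage(wn))) {
            n_zero_maps <<- n_zero_maps + 1L
            invokeRestart("muffleWarning")
          }
        })
    }
    tgt[[s]] <- quiet_log(maps[[2L]])
    ctl[[s]] <- quiet_log(neighbor_control_map(maps[[1L]], maps[[3L]]))
  }
  if (n_zero_maps > 0L)
    warnf("%d of %d maps were empty (bin norm below the noise tolerance)",
          n_zero_maps, 2L * nsubj)
  list(target = tgt, control = ctl)
}

#' Run the end-to-end synthetic demonstration experiment
#'
#' Simulates the full paradigm from known ground truth and runs every
#' analysis stage: leadfield + frequency-tagged sensor epochs, sensor
#' spectra with neighbor-bin peak statistics under both conditions,
#' peak-power condition contrast at the imagery rate, lateralization test
#' at the stimulus rate, minimum L1-norm source maps at both tagged bins
#' with neighbor-bin controls and cluster-corrected voxelwise tests, ROI
#' extraction with a repeated-measures ANOVA across the three
#' condition/frequency levels, and the intracranial high-gamma branch on
#' amplitude-modulated synthetic contacts.  The run is deterministic
#' given the config seed; statistics tables are written as CSV when
#' `out_dir` is given.
#'
#' @param cfg a [freqtag_config()]; its `sim` element carries the
#'   synthetic-data parameters.
#' @param lf optional [make_leadfield()]; default a 64-point 5 mm grid
#'   with 32 sensors (`random-incoherent`).
#' @param out_dir optional output directory for CSV tables and containers.
#' @param seeg run the intracranial branch too (default `TRUE`)?
#' @return list of class `run_report` with per-stage results and
#'   provenance.
#' @export
run_demo <- function(cfg = freqtag_config(), lf = NULL, out_dir = NULL,
                     seeg = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  lf <- lf %||% make_leadfield(grid = source_grid(c(4L, 4L, 4L), 5),
                               m_sensors = 32L, seed = cfg$seed,
                               mode = "random-incoherent")
  sim <- simulate_meg(cfg$sim, lf)

  sens <- lapply(sim[c("imagery", "baseline")], sensor_stage, cfg = cfg)
  sp_im <- sens$imagery$spectrum
  sp_bl <- sens$baseline$spectrum
  contrast_img <- condition_contrast(
    peak_power(sp_im$channel_average, sp_im$freqs, cfg$f_img),
    peak_power(sp_bl$channel_average, sp_bl$freqs, cfg$f_img), tails = "two")
  lat_stim <- lateralization_test(sp_im, cfg$f_stim)

  rlf <- reduce_orientations(lf)
  w <- depth_weights(rlf, cfg$depth_gamma)
  white_im <- prewhiten(sim$imagery)
  white_bl <- prewhiten(sim$baseline)
  maps_img <- source_stage_maps(white_im, rlf, w, cfg, cfg$f_img)
  maps_stim <- source_stage_maps(white_im, rlf, w, cfg, cfg$f_stim)
  maps_stim_bl <- source_stage_maps(white_bl, rlf, w, cfg, cfg$f_stim)
  cl_img <- voxelwise_cluster_test(maps_img$target, maps_img$control,
                                   voxel_alpha = cfg$voxel_alpha,
                                   cluster_alpha = cfg$cluster_alpha,
                                   n_perm = cfg$n_perm, seed = cfg$seed + 1L)
  cl_stim <- voxelwise_cluster_test(maps_stim$target, maps_stim$control,
                                    voxel_alpha = cfg$voxel_alpha,
                                    cluster_alpha = cfg$cluster_alpha,
                                    n_perm = cfg$n_perm, seed = cfg$seed + 2L)

  # ROI ANOVA across the three levels at the imagery-cluster peak
  anova_roi <- NULL
  if (length(cl_img$clusters)) {
    peak <- cl_img$clusters[[1L]]$peak
    roi_of <- function(maps) vapply(maps, roi_extract, numeric(1L), peak = peak)
    y <- array(c(roi_of(maps_img$target), roi_of(maps_stim$target),
                 roi_of(maps_stim_bl$target)),
               c(cfg$sim$n_subjects, 3L, 1L))
    anova_roi <- rm_anova_gg(y)
  }

  seeg_res <- NULL
  if (seeg) {
    rec_im <- simulate_seeg(mod_freqs = list(c(cfg$f_img, 0.4), c(cfg$f_stim, 0.4)),
                            seed = cfg$seed + 10L, condition = "imagery")
    rec_bl <- simulate_seeg(mod_freqs = list(c(cfg$f_stim, 0.4)),
                            seed = cfg$seed + 11L, condition = "baseline")
    spec_im <- envelope_spectrum(highgamma_envelope(rec_im, cfg$gamma_band),
                                 cfg$skip, cfg$window_length)
    spec_bl <- envelope_spectrum(highgamma_envelope(rec_bl, cfg$gamma_band),
                                 cfg$skip, cfg$window_length)
    peaks <- rbind(
      data.frame(value = trial_normalized_peaks(spec_im, cfg$f_img),
                 region = "STG", condition = "imagery"),
      data.frame(value = trial_normalized_peaks(spec_bl, cfg$f_img),
                 region = "STG", condition = "baseline"))
    seeg_res <- list(
      peak_stats_imagery = contact_peak_test(spec_im, cfg$band),
      peak_stats_baseline = contact_peak_test(spec_bl, cfg$band),
      region_stats = region_pool_test(peaks),
      zscore_imagery = zscore_spectrum(colMeans(spec_im$power), spec_im$freqs,
                                       cfg$band, c(cfg$f_img, cfg$f_stim)))
  }

  report <- structure(list(
    config = cfg, leadfield_mode = lf$mode,
    sensor = list(imagery = sens$imagery$peak_stats,
                  baseline = sens$baseline$peak_stats,
                  contrast_f_img = contrast_img,
                  lateralization_f_stim = lat_stim),
    source = list(clusters_f_img = cl_img, clusters_f_stim = cl_stim,
                  anova_roi = anova_roi),
    seeg = seeg_res,
    truth = sim$truth,
    provenance = list(hash = cfg$hash, seed = cfg$seed,
                      package_version = as.character(utils::packageVersion("freqtag")))),
    class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    header <- sprintf("# freqtag run %s (seed %d)", cfg$hash, cfg$seed)
    wr <- function(df, name) {
      path <- file.path(out_dir, name)
      writeLines(header, path)
      suppressWarnings(utils::write.table(df, path, append = TRUE, sep = ",",
                                          row.names = FALSE, quote = FALSE))
    }
    wr(report$sensor$imagery, "sensor_peaks_imagery.csv")
    wr(report$sensor$baseline, "sensor_peaks_baseline.csv")
    if (!is.null(seeg_res)) {
      wr(seeg_res$peak_stats_imagery, "seeg_peaks_imagery.csv")
      wr(seeg_res$region_stats$one_sample, "seeg_region_one_sample.csv")
    }
    write_container(sim$imagery, file.path(out_dir, "epochs_imagery"))
    write_container(lf, file.path(out_dir, "leadfield"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d, config %s\n", x$config$seed, x$config$hash))
  sig <- function(ps, f) {
    k <- which.min(abs(ps$freq - f))
    sprintf("t_%d = %.2f, p_fdr = %.3g, d = %.2f", ps$df[k], ps$t[k],
            ps$p_fdr[k], ps$cohens_d[k])
  }
  cat(sprintf("  sensor %g Hz (imagery):  %s\n", x$config$f_img,
              sig(x$sensor$imagery, x$config$f_img)))
  cat(sprintf("  sensor %g Hz (baseline): %s\n", x$config$f_img,
              sig(x$sensor$baseline, x$config$f_img)))
  cat(sprintf("  sensor %g Hz (imagery):  %s\n", x$config$f_stim,
              sig(x$sensor$imagery, x$config$f_stim)))
  cat(sprintf("  %d-cluster source map at %g Hz; %d at %g Hz\n",
              length(x$source$clusters_f_img$clusters), x$config$f_img,
              length(x$source$clusters_f_stim$clusters), x$config$f_stim))
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Plain key-value schema mirroring the arguments of [freqtag_config()]
#' and [sim_config()] (simulation keys nested under `sim:`).
#'
#' @param path YAML file path.
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  raw$sim <- NULL
  cfg_args <- raw
  if (length(sim_args)) cfg_args$sim <- do.call(sim_config, sim_args)
  do.call(freqtag_config, cfg_args)
}
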