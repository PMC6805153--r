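#' @importFrom graphics abline axis legend lines matplot points
NULL

#' Plot a channel-average power spectrum with tagged bins marked
#'
#' @param x a [power_spectrum()] object.
#' @param tags frequencies (Hz) to mark (default 0.8 and 4).
#' @param xlim frequency range shown.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.spectral_power <- function(x, tags = c(0.8, 4), xlim = c(0.3, 5), ...) {
  ca <- x$channel_average
  sel <- x$freqs >= xlim[1L] & x$freqs <= xlim[2L]
  matplot(x$freqs[sel], t(ca[, sel, drop = FALSE]), type = "l", lty = 1,
          col = grDevices::grey(0.75), xlab = "frequency (Hz)",
          ylab = "evoked power", ...)
  lines(x$freqs[sel], colMeans(ca)[sel], lwd = 2)
  abline(v = tags, lty = 3)
  invisible(x)
}

#' Plot an activation map as value against grid position
#'
#' Displays the per-voxel activation ordered by grid index with the peak
#' voxel highlighted — a compact diagnostic for sparse source maps on
#' abstract grids.
#'
#' @param x an [activation_map()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.activation_map <- function(x, ...) {
  graphics::plot(seq_along(x$values), x$values, type = "h",
                 xlab = "voxel index",
                 ylab = if (x$log_transformed) "log activation" else
                   "RMS activation", ...)
  pk <- which.max(x$values)
  points(pk, x$values[pk], pch = 19)
  invisible(x)
}
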