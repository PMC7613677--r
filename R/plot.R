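# Spectral display: magnitude or real spectrum against the ppm axis, with
# the axis reversed so ppm increases right to left.

#' Plot a spectrum from an MRS image
#'
#' Extracts one FID (by spatial and dynamic indices), Fourier-transforms it,
#' optionally phases it, and plots it against the chemical-shift axis with
#' ppm increasing right to left as conventionally displayed.
#'
#' @param image an `mrs_image`.
#' @param indices integer(3) spatial voxel indices (1-based).
#' @param dyn integer(3) indices into dimensions 5-7 (1-based; ignored for
#'   absent dimensions).
#' @param mode `"real"` or `"magnitude"`.
#' @param p0,p1 zeroth-order (radians) and first-order (radians/Hz) phase.
#' @param ref_shift ppm at zero offset; default per the image's nucleus.
#' @param ... passed to [graphics::plot()].
#' @return The plotted [ppm_axis()] and spectrum, invisibly.
#' @export
plot_spectrum <- function(image, indices = c(1L, 1L, 1L), dyn = c(1L, 1L, 1L),
                          mode = c("real", "magnitude"), p0 = 0, p1 = 0,
                          ref_shift = NULL, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "mrs_image"))
  d <- dims7(image$data)
  idx <- as.list(c(indices, 1L, dyn)[1:7])
  idx[[4]] <- seq_len(d[4])
  fid <- do.call(`[`, c(list(image$data), idx, drop = TRUE))
  f0 <- image$extension$spectrometer_frequency[1]
  if (is.null(ref_shift))
    ref_shift <- default_ref_shift(image$extension$resonant_nucleus[1])
  ax <- ppm_axis(d[4], image$header$pixdim[5], f0, ref_shift)
  spec <- apply_phase(fid_to_spectrum(fid), ax, p0 = p0, p1 = p1)
  y <- if (mode == "real") Re(spec) else Mod(spec)
  graphics::plot(ax$ppm, y, type = "l", xlim = rev(range(ax$ppm)),
                 xlab = "Chemical shift (ppm)",
                 ylab = paste0(toupper(substring(mode, 1, 1)),
                               substring(mode, 2), " signal (a.u.)"), ...)
  invisible(list(axis = ax, spectrum = spec))
}
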