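# Frequency and phase conventions made operational: chemical-shift axis,
# display transform, phasing, convention flip.
#
# Convention: the absolute (rotating-frame offset) frequency axis increases
# left to right, so the chemical-shift (ppm) axis increases right to left.
# A resonance at shift delta is stored with offset f = (ref_shift - delta) *
# f0_mhz Hz, realizing the omega = -gamma * B0 display rule. The DFT is
# unnormalized forward with 1/N on the inverse.

#' Chemical-shift axis for a spectrum
#'
#' Builds the display axis: DFT bin offsets in Hz spanning
#' `[-BW/2, +BW/2)` in ascending order (`BW = 1/dwell_s`), and the
#' corresponding ppm values `ref_shift - offsets_hz / f0_mhz`, which
#' therefore decrease left to right.
#'
#' @param n_points number of spectral points (>= 2).
#' @param dwell_s dwell time in seconds.
#' @param f0_mhz spectrometer frequency in MHz.
#' @param ref_shift ppm value at zero rotating-frame offset (e.g. 4.65 for
#'   water-referenced 1H at body temperature).
#' @return An object of class `mrs_axis`: list with `offsets_hz`, `ppm`,
#'   `ref_shift`, `f0_mhz`.
#' @examples
#' ax <- ppm_axis(4, dwell_s = 0.25, f0_mhz = 1, ref_shift = 0)
#' ax$offsets_hz   # -2 -1  0  1
#' ax$ppm          #  2  1  0 -1
#' @export
ppm_axis <- function(n_points, dwell_s, f0_mhz, ref_shift = 0) {
  stopifnot(n_points >= 2L, dwell_s > 0, f0_mhz > 0)
  bw <- 1 / dwell_s
  k <- seq_len(n_points) - 1L - floor(n_points / 2)
  offsets <- k * bw / n_points
  structure(list(offsets_hz = offsets,
                 ppm = ref_shift - offsets / f0_mhz,
                 ref_shift = ref_shift, f0_mhz = f0_mhz),
            class = "mrs_axis")
}

#' Default reference shift for a nucleus
#'
#' The ppm value assigned to zero rotating-frame offset. This is a display
#' parameter, not a physical constant: 4.65 ppm (water at body temperature)
#' for 1H, 0 otherwise. Override it wherever spectra are referenced
#' differently.
#'
#' @param nucleus nucleus string, e.g. `"1H"`.
#' @return ppm value.
#' @export
default_ref_shift <- function(nucleus) {
  if (identical(nucleus, "1H")) 4.65 else 0
}

# fftshift: reorder DFT output so frequencies ascend from -BW/2.
fftshift <- function(x) {
  n <- length(x)
  c(x[(floor(n / 2) + 1L):n], x[seq_len(floor(n / 2))])
}

#' Transform an FID to a display-ordered spectrum
#'
#' Unnormalized forward DFT of the FID, reordered (center-shifted) so that
#' element `i` corresponds to `ppm_axis()$offsets_hz[i]`, i.e. ascending
#' absolute frequency / descending ppm.
#'
#' @param fid complex vector.
#' @return complex vector of the same length.
#' @export
fid_to_spectrum <- function(fid) {
  stopifnot(length(fid) >= 1L)
  fftshift(stats::fft(as.complex(fid)))
}

#' Inverse of [fid_to_spectrum()]
#'
#' @param spectrum complex vector in display order.
#' @return complex FID.
#' @export
spectrum_to_fid <- function(spectrum) {
  n <- length(spectrum)
  unshifted <- c(spectrum[(n - floor(n / 2) + 1L):n],
                 spectrum[seq_len(n - floor(n / 2))])
  stats::fft(unshifted, inverse = TRUE) / n
}

#' Apply zeroth- and first-order phase to a spectrum
#'
#' `out[i] = spectrum[i] * exp(1i * (p0 + p1 * (offsets_hz[i] - pivot_hz)))`.
#' The bin at the pivot frequency is left unchanged by the first-order term.
#'
#' @param spectrum complex vector in display order.
#' @param axis matching [ppm_axis()].
#' @param p0 zeroth-order phase, radians.
#' @param p1 first-order phase, radians per Hz.
#' @param pivot_hz pivot frequency for the first-order term (default: zero
#'   offset, i.e. the reference shift).
#' @return phased complex vector.
#' @export
apply_phase <- function(spectrum, axis, p0 = 0, p1 = 0, pivot_hz = 0) {
  stopifnot(inherits(axis, "mrs_axis"))
  if (length(spectrum) != length(axis$offsets_hz))
    stop_mrs("spectrum and axis lengths differ", "mrs_shape_error")
  spectrum * exp(1i * (p0 + p1 * (axis$offsets_hz - pivot_hz)))
}

#' Flip the frequency convention of an FID
#'
#' Element-wise complex conjugation: the spectrum of the result is the
#' mirror image of the original about zero offset. Used to repair data
#' stored with the opposite sign convention. Applying it twice is the
#' identity, and real-valued FIDs are unchanged.
#'
#' @param fid complex vector or array.
#' @return conjugated FID, same shape.
#' @export
flip_frequency_convention <- function(fid) Conj(fid)
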