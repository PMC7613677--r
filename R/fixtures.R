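# Synthetic data: Lorentzian-peak FID simulator and a small suite of example
# datasets exercising every feature of the format (dynamic dimensions,
# dynamic headers, privacy-flagged keys, provenance), so that everything is
# testable without downloads.

#' Declare a synthetic acquisition
#'
#' @param peaks data frame (or list coercible to one) with columns `shift`
#'   (ppm), `amplitude` (arbitrary units), `lw` (Lorentzian linewidth, FWHM
#'   in Hz, > 0), `phase` (radians).
#' @param n_points FID length.
#' @param dwell_s dwell time, seconds.
#' @param f0_mhz spectrometer frequency, MHz.
#' @param nucleus nucleus string.
#' @param ref_shift ppm at zero offset; defaults per
#'   [default_ref_shift()].
#' @param noise_sd standard deviation of the complex Gaussian noise added to
#'   each FID point (per real/imaginary component).
#' @param seed RNG seed; identical (spec, seed) gives identical output.
#' @return A list of class `mrs_synthetic_spec`.
#' @export
synthetic_spec <- function(peaks, n_points = 512L, dwell_s = 5e-4,
                           f0_mhz = 123.2, nucleus = "1H",
                           ref_shift = default_ref_shift(nucleus),
                           noise_sd = 0, seed = 1L) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) > 0L) {
    stopifnot(all(c("shift", "amplitude", "lw") %in% names(peaks)))
    if (is.null(peaks$phase)) peaks$phase <- 0
    stopifnot(all(peaks$lw > 0))
  }
  stopifnot(n_points >= 1L, dwell_s > 0, f0_mhz > 0)
  structure(list(peaks = peaks, n_points = as.integer(n_points),
                 dwell_s = dwell_s, f0_mhz = f0_mhz, nucleus = nucleus,
                 ref_shift = ref_shift, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "mrs_synthetic_spec")
}

#' Simulate a Lorentzian-peak FID
#'
#' Sum of exponentially decaying complex tones,
#' `s(t_k) = sum_p A_p exp(1i phi_p) exp(1i 2 pi f_p t_k) exp(-pi lw_p t_k)`
#' with rotating-frame offset `f_p = (ref_shift - shift_p) * f0_mhz` Hz and
#' `t_k = k * dwell_s` (k from 0), plus seeded complex Gaussian noise. The
#' offset sign realizes the display convention: resonances at higher ppm
#' than the reference acquire negative offsets and display left of it.
#'
#' @param spec an [synthetic_spec()].
#' @return complex vector of length `n_points`.
#' @export
simulate_fid <- function(spec) {
  stopifnot(inherits(spec, "mrs_synthetic_spec"))
  t_k <- (seq_len(spec$n_points) - 1L) * spec$dwell_s
  s <- complex(real = numeric(spec$n_points), imaginary = numeric(spec$n_points))
  if (nrow(spec$peaks) > 0L) {
    for (p in seq_len(nrow(spec$peaks))) {
      f_p <- (spec$ref_shift - spec$peaks$shift[p]) * spec$f0_mhz
      s <- s + spec$peaks$amplitude[p] * exp(1i * spec$peaks$phase[p]) *
        exp(1i * 2 * pi * f_p * t_k) * exp(-pi * spec$peaks$lw[p] * t_k)
    }
  }
  if (spec$noise_sd > 0) {
    s <- s + with_seed(spec$seed, complex(
      real = rnorm(spec$n_points, sd = spec$noise_sd),
      imaginary = rnorm(spec$n_points, sd = spec$noise_sd)))
  }
  s
}

# water + NAA-like peak list used by the 1H examples
h1_peaks <- function() data.frame(
  shift = c(4.65, 2.01), amplitude = c(5, 1), lw = c(8, 6), phase = c(0, 0))

#' Generate an example NIfTI-MRS dataset
#'
#' Four small, fully synthetic datasets exercising the format's features:
#' \describe{
#'   \item{svs_raw}{1x1x1xN x coils x dynamics single-voxel 1H data before
#'     preprocessing: `dim_5 = DIM_COIL` (with per-coil complex weights),
#'     `dim_6 = DIM_DYN`.}
#'   \item{mrsi_proc}{8x8x1xN processed 31P spectroscopic imaging with
#'     standard keys including privacy-flagged subject identifiers and a
#'     processing-provenance trail.}
#'   \item{edited}{1x1x1xN x coils x dynamics x 2 spectral-editing data:
#'     `dim_7 = DIM_EDIT` with a per-element `EditCondition` dynamic header
#'     and prefilled provenance.}
#'   \item{fingerprint}{1x1x1xN x M acquisition-parameter series where four
#'     parameters change together along one dimension: `dim_5 = DIM_USER_0`
#'     with four parallel length-M arrays in `dim_5_header`.}
#' }
#' All sizes are kept small (N <= 1024, grids <= 8x8) so suites built on
#' them run in seconds. Output is deterministic in (kind, seed).
#'
#' @param kind one of `"svs_raw"`, `"mrsi_proc"`, `"edited"`,
#'   `"fingerprint"`.
#' @param seed RNG seed.
#' @return A conformant `mrs_image`.
#' @export
gen_example <- function(kind = c("svs_raw", "mrsi_proc", "edited", "fingerprint"),
                        seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    svs_raw = {
      n <- 512L; n_coil <- 4L; n_dyn <- 16L
      spec <- synthetic_spec(h1_peaks(), n_points = n, noise_sd = 0.02,
                             seed = seed)
      base <- simulate_fid(spec)
      weights <- with_seed(seed + 1L, complex(real = rnorm(n_coil, sd = 1),
                                              imaginary = rnorm(n_coil, sd = 1)))
      data <- array(0i, dim = c(1L, 1L, 1L, n, n_coil, n_dyn))
      noise <- with_seed(seed + 2L, complex(
        real = rnorm(n * n_coil * n_dyn, sd = 0.05),
        imaginary = rnorm(n * n_coil * n_dyn, sd = 0.05)))
      idx <- 1L
      for (dyn in seq_len(n_dyn)) for (coil in seq_len(n_coil)) {
        data[1, 1, 1, , coil, dyn] <- weights[coil] * base +
          noise[idx:(idx + n - 1L)]
        idx <- idx + n
      }
      img <- mrs_make_minimal(data, dwell_s = spec$dwell_s,
                              f0_mhz = spec$f0_mhz, nucleus = "1H")
      img <- mrs_edit_key(img, "EchoTime", 0.011)
      img <- mrs_edit_key(img, "RepetitionTime", 5)
      img <- mrs_edit_key(img, "WaterSuppressed", FALSE)
      img
    },
    mrsi_proc = {
      nx <- 8L; ny <- 8L; n <- 256L
      spec31p <- synthetic_spec(
        data.frame(shift = c(0, 4.8, -2.5), amplitude = c(3, 1, 1.2),
                   lw = c(10, 12, 14), phase = 0),
        n_points = n, dwell_s = 2.5e-4, f0_mhz = 49.9, nucleus = "31P",
        ref_shift = 0, noise_sd = 0, seed = seed)
      base <- simulate_fid(spec31p)
      amp <- with_seed(seed + 1L, matrix(runif(nx * ny, 0.5, 1.5), nx, ny))
      data <- array(0i, dim = c(nx, ny, 1L, n))
      for (i in seq_len(nx)) for (j in seq_len(ny))
        data[i, j, 1, ] <- amp[i, j] * base
      geom <- geometry(rbind(cbind(diag(c(10, 10, 15)), c(-40, -40, 0)),
                             c(0, 0, 0, 1)), frame_code = 1L)
      img <- mrs_make_minimal(data, dwell_s = spec31p$dwell_s,
                              f0_mhz = spec31p$f0_mhz, nucleus = "31P",
                              geometry = geom)
      img <- mrs_edit_key(img, "EchoTime", 0.00023)
      img <- mrs_edit_key(img, "RepetitionTime", 1)
      img <- mrs_edit_key(img, "SequenceName", "csi_fid")
      img <- mrs_edit_key(img, "Manufacturer", "Synthetic")
      img <- mrs_edit_key(img, "SoftwareVersions", "sim1.0")
      img <- mrs_edit_key(img, "PatientName", "SYNTHETIC^PHANTOM")
      img <- mrs_edit_key(img, "PatientID", "SYN-0001")
      img <- mrs_edit_key(img, "PatientDoB", "19000101")
      img <- append_provenance(img, provenance_entry(
        "Spatial reconstruction", "mrsnifti-sim",
        as.character(utils::packageVersion("mrsnifti")),
        "synthetic example data"))
      img
    },
    edited = {
      n <- 512L; n_coil <- 2L; n_dyn <- 4L
      on_peaks <- rbind(h1_peaks(),
                        data.frame(shift = 3.0, amplitude = 0.5, lw = 10, phase = 0))
      data <- array(0i, dim = c(1L, 1L, 1L, n, n_coil, n_dyn, 2L))
      weights <- with_seed(seed + 1L, complex(real = rnorm(n_coil),
                                              imaginary = rnorm(n_coil)))
      for (cond in 1:2) {
        pk <- if (cond == 1L) on_peaks else h1_peaks()
        base <- simulate_fid(synthetic_spec(pk, n_points = n,
                                            noise_sd = 0.02,
                                            seed = seed + cond))
        for (dyn in seq_len(n_dyn)) for (coil in seq_len(n_coil))
          data[1, 1, 1, , coil, dyn, cond] <- weights[coil] * base
      }
      img <- mrs_make_minimal(data, dwell_s = 5e-4, f0_mhz = 123.2,
                              nucleus = "1H",
                              dim_tags = list("7" = "DIM_EDIT"))
      img <- set_dim_tag(img, 7L, "DIM_EDIT",
                         header = list(EditCondition = c("ON", "OFF")))
      img <- mrs_edit_key(img, "EchoTime", 0.068)
      img <- append_provenance(img, provenance_entry(
        "Frequency and phase alignment", "mrsnifti-sim",
        as.character(utils::packageVersion("mrsnifti")), "synthetic"))
      img <- append_provenance(img, provenance_entry(
        "Coil combination", "mrsnifti-sim",
        as.character(utils::packageVersion("mrsnifti")), "synthetic"))
      img
    },
    fingerprint = {
      n <- 256L; m <- 20L
      te <- seq(0.01, 0.2, length.out = m)
      tr <- seq(0.5, 3, length.out = m)
      fa <- round(seq(20, 90, length.out = m), 1)
      ti <- seq(0.05, 1, length.out = m)
      data <- array(0i, dim = c(1L, 1L, 1L, n, m))
      for (k in seq_len(m)) {
        wt <- exp(-te[k] / 0.08) * (1 - exp(-tr[k] / 1.3)) * sin(fa[k] * pi / 180)
        base <- simulate_fid(synthetic_spec(h1_peaks(), n_points = n,
                                            noise_sd = 0.01, seed = seed + k))
        data[1, 1, 1, , k] <- wt * base
      }
      img <- mrs_make_minimal(data, dwell_s = 5e-4, f0_mhz = 123.2,
                              nucleus = "1H",
                              dim_tags = list("5" = "DIM_USER_0"))
      img <- set_dim_tag(img, 5L, "DIM_USER_0",
                         info = "fingerprinting parameter set",
                         header = list(EchoTime = te, RepetitionTime = tr,
                                       ExcitationFlipAngle = fa,
                                       InversionTime = ti))
      img
    })
}
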