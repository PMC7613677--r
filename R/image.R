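# The in-memory unit of all I/O: complex data array + NIfTI header fields +
# header extension.

# Default header-field list. R index i of dim/pixdim corresponds to NIfTI
# index i-1, i.e. dim[1] is the rank and pixdim[1] the qfac slot.
default_header <- function() {
  list(
    dim = c(4L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    pixdim = c(1, 1, 1, 1, 1, 1, 1, 1),
    datatype = DT_COMPLEX64,
    intent_name = sprintf("mrs_v%d_%d", MRS_STANDARD_VERSION[["major"]],
                          MRS_STANDARD_VERSION[["minor"]]),
    xyzt_units = XYZT_MM_SEC,
    qform_code = 0L, sform_code = 0L,
    quatern = c(b = 0, c = 0, d = 0),
    qoffset = c(x = 0, y = 0, z = 0),
    srow = matrix(0, 3, 4),
    descrip = ""
  )
}

#' Construct an MRS image
#'
#' Bundles the complex data array (rank 4-7: x, y, z, FID time, up to three
#' dynamic dimensions), the NIfTI-2 header fields, and the JSON header
#' extension. Use [mrs_make_minimal()] for the common case; this constructor
#' performs only structural coercion so that non-conformant objects can be
#' built and then inspected with [mrs_validate()].
#'
#' @param data complex array of rank 4-7.
#' @param extension an [mrs_extension()].
#' @param header optional list of NIfTI header fields; missing fields take
#'   defaults (unlocalized geometry, single-precision complex datatype,
#'   mm/seconds units). `dim`/`pixdim` are completed from `data` and
#'   `dwell_s` if absent.
#' @param dwell_s sampling interval of the FID in seconds, stored in
#'   `pixdim[4]` (NIfTI numbering).
#' @return An object of class `mrs_image`.
#' @export
mrs_image <- function(data, extension, header = list(), dwell_s = NULL) {
  stopifnot(is.array(data) || is.vector(data))
  if (!is.complex(data)) data <- array(as.complex(data), dim = dims7(data))
  hdr <- utils::modifyList(default_header(), header)
  d <- dims7(data)
  rank <- max(4L, length(dim(data) %||% 1L))
  if (is.null(header$dim)) hdr$dim <- c(rank, as.integer(d[1:7]))
  if (!is.null(dwell_s)) hdr$pixdim[5] <- dwell_s
  dim(data) <- d   # internally padded with singletons; hdr$dim holds the declared rank
  structure(list(data = data, header = hdr, extension = extension),
            class = "mrs_image")
}

#' @export
print.mrs_image <- function(x, ...) {
  d <- x$header$dim
  cat(sprintf("<mrs_image> %s  rank %d\n",
              paste(d[seq_len(d[1]) + 1L], collapse = " x "), d[1]))
  cat(sprintf("  nucleus: %s @ %s MHz; dwell %g s (bandwidth %g Hz)\n",
              paste(x$extension$resonant_nucleus, collapse = ","),
              paste(format(x$extension$spectrometer_frequency), collapse = ","),
              x$header$pixdim[5], 1 / x$header$pixdim[5]))
  for (n in names(x$extension$dim_tags))
    cat(sprintf("  dim_%s: %s\n", n, x$extension$dim_tags[[n]]))
  invisible(x)
}

# Fig-1 default purposes for the dynamic dimensions.
DEFAULT_DIM_TAGS <- c("5" = "DIM_COIL", "6" = "DIM_DYN", "7" = "DIM_INDIRECT")

#' Build a minimally conformant MRS image
#'
#' Wraps an FID (or FID array) into an `mrs_image` that passes
#' [mrs_validate()] with exactly the two mandatory metadata keys (plus any
#' dimension tags implied by the array shape). A rank-1 input becomes a
#' 1x1x1xN single-voxel array; rank 2-3 inputs are treated as FID x dynamic
#' dimensions and get three leading singleton spatial dimensions; rank 4-7
#' inputs are used as-is. Used dynamic dimensions without an explicit tag
#' take the standard's defaults: coils (5), repeated measurements (6),
#' indirect frequency (7).
#'
#' @param fid complex array, rank 1-7.
#' @param dwell_s dwell time (sampling interval) in seconds; > 0.
#' @param f0_mhz spectrometer frequency(ies) in MHz.
#' @param nucleus resonant nucleus string(s), e.g. `"1H"`.
#' @param geometry optional 4x4 affine (voxel index to mm, NIfTI
#'   convention) or a [geometry()] object; absent means unlocalized, which
#'   stores the 10 m default voxel size with `qform_code = 0`.
#' @param dim_tags optional named list overriding the default dimension
#'   tags, names in `c("5","6","7")`.
#' @param precision `"single"` (datatype code 32, the default) or
#'   `"double"` (code 1792).
#' @return A conformant `mrs_image`.
#' @examples
#' img <- mrs_make_minimal(complex(real = rnorm(512), imaginary = rnorm(512)),
#'                         dwell_s = 5e-4, f0_mhz = 123.2, nucleus = "1H")
#' mrs_validate(img)$conformant
#' @export
mrs_make_minimal <- function(fid, dwell_s, f0_mhz, nucleus, geometry = NULL,
                             dim_tags = list(), precision = c("single", "double")) {
  precision <- match.arg(precision)
  if (length(fid) == 0L) stop_mrs("empty FID", "mrs_empty_error")
  if (!is_scalar_number(dwell_s) || dwell_s <= 0)
    stop_mrs("dwell_s must be a positive number of seconds", "mrs_dwell_error")
  d <- dim(fid) %||% length(fid)
  if (length(d) > 7L) stop_mrs("rank above 7 is not storable", "mrs_rank_error")
  if (length(d) < 4L) d <- c(1L, 1L, 1L, d)   # leading spatial singletons
  data <- array(as.complex(fid), dim = d)

  tags <- lapply(dim_tags, as.character)
  for (n in 5:7) {
    key <- as.character(n)
    if (length(d) >= n && d[n] > 1L && is.null(tags[[key]]))
      tags[[key]] <- DEFAULT_DIM_TAGS[[key]]
  }
  ext <- mrs_extension(spectrometer_frequency = f0_mhz,
                       resonant_nucleus = nucleus, dim_tags = tags)

  hdr <- default_header()
  hdr$dim <- NULL   # let mrs_image derive the shape from the data
  hdr$datatype <- if (precision == "single") DT_COMPLEX64 else DT_COMPLEX128
  hdr$pixdim[5] <- dwell_s
  if (is.null(geometry)) {
    g <- default_unlocalized_geometry()
    hdr <- apply_geometry(hdr, g)
  } else {
    if (is.matrix(geometry)) geometry <- geometry(geometry, frame_code = 1L)
    hdr <- apply_geometry(hdr, geometry)
  }
  mrs_image(data, ext, header = hdr)
}

# Intent-name pattern carrying the standard version.
INTENT_RE <- "^mrs_v([0-9]+)_([0-9]+)$"

parse_intent_version <- function(intent_name) {
  m <- regmatches(intent_name, regexec(INTENT_RE, intent_name))[[1]]
  if (length(m) == 0L) return(NULL)
  c(major = as.integer(m[2]), minor = as.integer(m[3]))
}

# ---- conformance validation ---------------------------------------------

finding <- function(severity, code, path, message) {
  list(severity = severity, code = code, path = path, message = message)
}

#' Validate an MRS image against the standard
#'
#' Checks every conformance rule from the standard that applies to the
#' in-memory object: rank 4-7, complex datatype, positive dwell time,
#' versioned `intent_name`, the two mandatory metadata keys, a tag for
#' every used dynamic dimension (drawn from the tag vocabulary), long-form
#' dynamic-header lengths, the spatial conformance rule (localized qform or
#' unlocalized default), and well-formed provenance entries. Unknown
#' capitalized keys and standard versions newer than the one implemented
#' here yield warnings, not errors: user-defined keys are explicitly
#' permitted.
#'
#' @param image an `mrs_image`.
#' @return An object of class `mrs_report`: list with `findings` (each a
#'   list with `severity`, `code`, `path`, `message`) and `conformant`
#'   (`TRUE` iff no finding has severity `"error"`).
#' @export
mrs_validate <- function(image) {
  stopifnot(inherits(image, "mrs_image"))
  hdr <- image$header
  ext <- image$extension
  f <- list()
  add <- function(severity, code, path, message)
    f[[length(f) + 1L]] <<- finding(severity, code, path, message)

  rank <- hdr$dim[1]
  if (!(rank >= 4L && rank <= 7L))
    add("error", "RANK_OUT_OF_RANGE", "header.dim",
        sprintf("data rank %d outside the allowed 4-7", rank))
  if (!hdr$datatype %in% c(DT_COMPLEX64, DT_COMPLEX128))
    add("error", "NON_COMPLEX_DATATYPE", "header.datatype",
        sprintf("datatype code %d is not a complex type (32 or 1792)", hdr$datatype))
  if (!is_scalar_number(hdr$pixdim[5]) || hdr$pixdim[5] <= 0)
    add("error", "NONPOSITIVE_DWELL", "header.pixdim[4]",
        "dwell time (pixdim[4]) must be > 0")
  ver <- parse_intent_version(hdr$intent_name)
  if (is.null(ver))
    add("error", "BAD_INTENT_NAME", "header.intent_name",
        sprintf("intent_name '%s' does not match mrs_v{major}_{minor}", hdr$intent_name))
  else if (ver[["major"]] > MRS_STANDARD_VERSION[["major"]] ||
           (ver[["major"]] == MRS_STANDARD_VERSION[["major"]] &&
            ver[["minor"]] > MRS_STANDARD_VERSION[["minor"]]))
    add("warning", "VERSION_AHEAD", "header.intent_name",
        sprintf("file declares standard version %d.%d, newer than the %d.%d implemented here",
                ver[["major"]], ver[["minor"]],
                MRS_STANDARD_VERSION[["major"]], MRS_STANDARD_VERSION[["minor"]]))

  # mandatory keys
  sf <- ext$spectrometer_frequency
  if (is.null(sf) || length(sf) == 0L)
    add("error", "MISSING_MANDATORY_KEY", "ext.SpectrometerFrequency",
        "SpectrometerFrequency must be present")
  else if (!is.numeric(sf) || any(!is.finite(sf)) || any(sf <= 0))
    add("error", "BAD_MANDATORY_TYPE", "ext.SpectrometerFrequency",
        "SpectrometerFrequency must be positive MHz values")
  rn <- ext$resonant_nucleus
  if (is.null(rn) || length(rn) == 0L)
    add("error", "MISSING_MANDATORY_KEY", "ext.ResonantNucleus",
        "ResonantNucleus must be present")
  else if (!is.character(rn) || any(!nzchar(rn)))
    add("error", "BAD_MANDATORY_TYPE", "ext.ResonantNucleus",
        "ResonantNucleus must be non-empty strings")

  # dynamic dimensions
  d <- c(hdr$dim[-1], rep(1L, 7L))[1:7]
  for (n in 5:7) {
    key <- as.character(n)
    tag <- ext$dim_tags[[key]]
    if (d[n] > 1L && is.null(tag))
      add("error", "MISSING_DIM_TAG", paste0("ext.dim_", n),
          sprintf("dimension %d is used (size %d) but has no dim_%d tag", n, d[n], n))
    if (!is.null(tag) && !tag %in% valid_dim_tags())
      add("error", "UNKNOWN_DIM_TAG", paste0("ext.dim_", n),
          sprintf("dim_%d tag '%s' is not in the tag vocabulary", n, tag))
    hd <- ext$dim_headers[[key]]
    if (!is.null(hd)) {
      for (nm in names(hd)) {
        len <- dyn_length(hd[[nm]])
        if (!is.na(len) && len != d[n])
          add("error", "DIM_HEADER_LENGTH",
              sprintf("ext.dim_%d_header.%s", n, nm),
              sprintf("long-form array has length %d but dimension %d has size %d",
                      len, n, d[n]))
      }
    }
  }

  # spatial conformance
  vox <- hdr$pixdim[2:4]
  vox_ok <- is.numeric(vox) && all(is.finite(vox)) && all(vox > 0)
  if (hdr$qform_code > 0) {
    q <- hdr$quatern
    qn <- sum(q^2)
    geo_ok <- all(is.finite(q)) && all(is.finite(hdr$qoffset)) &&
      hdr$pixdim[1] %in% c(-1, 1) && vox_ok
    if (!geo_ok)
      add("error", "BAD_SPATIAL", "header.qform",
          "qform_code > 0 requires quaternion, offsets, qfac (+-1) and positive voxel sizes")
    else if (qn > 1 + 1e-6)
      add("error", "BAD_QUATERNION", "header.quatern",
          sprintf("quaternion b^2+c^2+d^2 = %.8f exceeds 1", qn))
  } else if (!vox_ok) {
    add("error", "BAD_SPATIAL", "header.pixdim",
        "qform_code == 0 requires positive voxel sizes (default 10 m) in pixdim[1..3]")
  }

  # provenance
  if (length(ext$processing_applied) > 0L) {
    for (i in seq_along(ext$processing_applied)) {
      e <- ext$processing_applied[[i]]
      if (!is.list(e) || !is_scalar_string(e$Method %||% "") ||
          !is_scalar_string(e$Program %||% "") ||
          !is_scalar_string(e$Version %||% ""))
        add("error", "BAD_PROVENANCE",
            sprintf("ext.ProcessingApplied[%d]", i - 1L),
            "provenance entries require Method, Program and Version")
    }
  }

  # unknown capitalized keys: permitted, but probably typos of standard keys
  for (nm in names(ext$user_keys))
    if (grepl("^[A-Z]", nm))
      add("warning", "UNKNOWN_STANDARD_KEY", paste0("ext.", nm),
          sprintf("'%s' looks standard-defined but is not in the registry", nm))

  structure(list(findings = f,
                 conformant = !any(vapply(f, function(x) x$severity == "error",
                                          logical(1)))),
            class = "mrs_report")
}

#' @export
print.mrs_report <- function(x, ...) {
  cat(if (x$conformant) "CONFORMANT" else "NOT CONFORMANT",
      sprintf("(%d finding%s)\n", length(x$findings),
              if (length(x$findings) == 1) "" else "s"))
  for (f in x$findings)
    cat(sprintf("  [%s] %s at %s: %s\n", f$severity, f$code, f$path, f$message))
  invisible(x)
}

#' @export
as.data.frame.mrs_report <- function(x, ...) {
  if (length(x$findings) == 0L)
    return(data.frame(severity = character(0), code = character(0),
                      path = character(0), message = character(0)))
  do.call(rbind, lapply(x$findings, as.data.frame))
}

report_codes <- function(report, severity = "error") {
  vapply(Filter(function(f) f$severity == severity, report$findings),
         `[[`, character(1), "code")
}
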