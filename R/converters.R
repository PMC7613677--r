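# Conversion of text-based spectroscopy formats (LCModel RAW/H2O, jMRUI
# text, plain two-column ASCII). None of these formats carries orientation,
# so every conversion uses the unlocalized default geometry; metadata the
# source omits must be supplied via overrides. Each successful conversion
# appends exactly one provenance entry and is deterministic: identical input
# bytes and overrides give identical output.

#' Conversion overrides
#'
#' User-supplied values filling gaps the source format omits. Values pass
#' the same checks as [mrs_make_minimal()].
#'
#' @param dwell_s dwell time, seconds.
#' @param f0_mhz spectrometer frequency, MHz.
#' @param nucleus nucleus string.
#' @param ref_shift reference shift, ppm.
#' @param note free-text provenance note.
#' @return A list of class `mrs_overrides`.
#' @export
conversion_overrides <- function(dwell_s = NULL, f0_mhz = NULL, nucleus = NULL,
                                 ref_shift = NULL, note = NULL) {
  structure(list(dwell_s = dwell_s, f0_mhz = f0_mhz, nucleus = nucleus,
                 ref_shift = ref_shift, note = note), class = "mrs_overrides")
}

as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    return(list(lines = readLines(text, warn = FALSE), source = basename(text)))
  if (length(text) == 1L) return(list(lines = strsplit(text, "\n")[[1]],
                                      source = "<text>"))
  list(lines = as.character(text), source = "<text>")
}

conversion_provenance <- function(img, format, source, note = NULL) {
  details <- sprintf("converted from %s (%s)", format, source)
  if (!is.null(note)) details <- paste0(details, "; ", note)
  append_provenance(img, provenance_entry(
    method = paste("format conversion from", format),
    program = "mrsnifti",
    version = as.character(utils::packageVersion("mrsnifti")),
    details = details))
}

pair_to_complex <- function(values, what) {
  if (length(values) == 0L || length(values) %% 2L != 0L)
    stop_mrs(sprintf("%s: expected real/imaginary pairs, got %d values",
                     what, length(values)), "mrs_pairing_error")
  complex(real = values[c(TRUE, FALSE)], imaginary = values[c(FALSE, TRUE)])
}

#' Convert LCModel RAW / H2O text data
#'
#' Parses the FORTRAN-namelist header blocks (`$SEQPAR` / `$NMID` ...
#' `$END`) followed by whitespace-separated real/imaginary pairs. Field
#' mapping: `HZPPPM` (Hz per ppm, numerically MHz) to
#' `SpectrometerFrequency`, `DELTAT` (s) to the dwell time, `ECHOT` (ms) to
#' the `EchoTime` standard key (converted to seconds). Dialect tolerance:
#' keys are case-insensitive, values may be quoted, separators may be commas
#' or newlines. H2O reference files convert the same way as independent
#' files.
#'
#' @param text path to a `.RAW`/`.H2O` file, or its contents as a string /
#'   character vector of lines.
#' @param overrides a [conversion_overrides()]; required when the header
#'   omits `DELTAT` or `HZPPPM`.
#' @return A conformant `mrs_image`.
#' @export
from_lcmodel_raw <- function(text, overrides = conversion_overrides()) {
  src <- as_lines(text)
  lines <- src$lines
  # namelist blocks: $NAME ... $END (case-insensitive)
  starts <- grep("^\\s*\\$(?i:[a-z]+)\\s*$|^\\s*\\$", lines, perl = TRUE)
  ends <- grep("^\\s*\\$\\s*(?i:END)\\s*$", lines, perl = TRUE)
  params <- list()
  data_start <- 1L
  if (length(ends) > 0L) {
    data_start <- max(ends) + 1L
    hdr_lines <- lines[seq_len(max(ends))]
    hdr_lines <- hdr_lines[!grepl("^\\s*\\$", hdr_lines) |
                             grepl("=", hdr_lines)]   # keep "$FOO key=..." one-liners
    body <- paste(gsub("^\\s*\\$\\w+", "", hdr_lines), collapse = ",")
    # split on commas/newlines outside quotes, then key = value
    for (piece in strsplit(body, ",")[[1]]) {
      if (!grepl("=", piece)) next
      kv <- strsplit(piece, "=", fixed = TRUE)[[1]]
      key <- toupper(trimws(kv[1]))
      val <- trimws(paste(kv[-1], collapse = "="))
      val <- gsub("^['\"]|['\"]$", "", val)
      if (nzchar(key)) params[[key]] <- val
    }
  }
  values <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[data_start:length(lines)]), "\\s+"))))
  values <- values[!is.na(values)]
  fid <- pair_to_complex(values, "LCModel RAW data block")

  f0 <- overrides$f0_mhz %||% (if (!is.null(params$HZPPPM)) as.numeric(params$HZPPPM))
  dwell <- overrides$dwell_s %||% (if (!is.null(params$DELTAT)) as.numeric(params$DELTAT))
  if (is.null(f0) || is.null(dwell))
    stop_mrs("LCModel header lacks HZPPPM and/or DELTAT and no override was given",
             "mrs_metadata_error")
  nucleus <- overrides$nucleus %||% "1H"
  img <- mrs_make_minimal(fid, dwell_s = dwell, f0_mhz = f0, nucleus = nucleus)
  if (!is.null(params$ECHOT))
    img <- mrs_edit_key(img, "EchoTime", as.numeric(params$ECHOT) / 1000)
  if (!is.null(params$ID))
    img <- mrs_edit_key(img, "OriginalFile", as.character(params$ID))
  conversion_provenance(img, "LCModel RAW", src$source, overrides$note)
}

#' Convert jMRUI text data
#'
#' Parses `Key: value` header lines (`PointsInDataset`, `DatasetsInFile`,
#' `SamplingInterval` in ms, `TransmitterFrequency` in Hz, `TypeOfNucleus`)
#' followed by whitespace-separated numeric columns; the first two columns
#' are the real and imaginary FID (any spectrum columns are ignored — the
#' spectrum is derivable). Unit conversions applied: ms to s, Hz to MHz.
#' Multiple signals are stacked into dimension 5 tagged `DIM_USER_0` with
#' info `"jMRUI signal index"`.
#'
#' @inheritParams from_lcmodel_raw
#' @return A conformant `mrs_image`.
#' @export
from_jmrui_text <- function(text, overrides = conversion_overrides()) {
  src <- as_lines(text)
  lines <- src$lines
  params <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z][A-Za-z0-9 ]*?)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) params[[gsub(" ", "", m[2])]] <- trimws(m[3])
  }
  num_re <- "^\\s*[-+0-9.eE]+(\\s+[-+0-9.eE]+)+\\s*$"
  data_lines <- lines[grepl(num_re, lines)]
  rows <- lapply(strsplit(trimws(data_lines), "\\s+"), as.numeric)
  rows <- Filter(function(r) !any(is.na(r)) && length(r) >= 2L, rows)
  n_rows <- length(rows)
  if (n_rows == 0L) stop_mrs("no numeric data rows found", "mrs_metadata_error")
  re <- vapply(rows, `[[`, numeric(1), 1L)
  im <- vapply(rows, `[[`, numeric(1), 2L)

  npts <- if (!is.null(params$PointsInDataset)) as.integer(params$PointsInDataset)
          else n_rows
  nsig <- if (!is.null(params$DatasetsInFile)) as.integer(params$DatasetsInFile) else 1L
  if (npts * nsig != n_rows)
    stop_mrs(sprintf("header declares %d points x %d datasets but %d rows were parsed",
                     npts, nsig, n_rows), "mrs_consistency_error")
  dwell <- overrides$dwell_s %||%
    (if (!is.null(params$SamplingInterval)) as.numeric(params$SamplingInterval) / 1000)
  f0 <- overrides$f0_mhz %||%
    (if (!is.null(params$TransmitterFrequency)) as.numeric(params$TransmitterFrequency) / 1e6)
  nucleus <- overrides$nucleus %||% params$TypeOfNucleus %||% NULL
  if (is.null(dwell) || is.null(f0) || is.null(nucleus) || !nzchar(nucleus))
    stop_mrs("jMRUI header lacks dwell/frequency/nucleus and no override was given",
             "mrs_metadata_error")

  fid <- complex(real = re, imaginary = im)
  if (nsig > 1L) {
    data <- array(fid, dim = c(npts, nsig))
    img <- mrs_make_minimal(data, dwell_s = dwell, f0_mhz = f0,
                            nucleus = nucleus,
                            dim_tags = list("5" = "DIM_USER_0"))
    img <- mrs_edit_key(img, "dim_5_info", "jMRUI signal index")
  } else {
    img <- mrs_make_minimal(fid, dwell_s = dwell, f0_mhz = f0, nucleus = nucleus)
  }
  conversion_provenance(img, "jMRUI text", src$source, overrides$note)
}

#' Convert a plain two-column ASCII FID
#'
#' The table has two numeric columns (real, imaginary); all metadata must be
#' supplied through `meta`.
#'
#' @param table path, character lines, or a two-column matrix / data frame.
#' @param meta a [conversion_overrides()] supplying at least `dwell_s`,
#'   `f0_mhz` and `nucleus`.
#' @return A conformant `mrs_image`.
#' @export
from_ascii <- function(table, meta) {
  source <- "<table>"
  if (is.character(table)) {
    src <- as_lines(table)
    source <- src$source
    values <- suppressWarnings(as.numeric(unlist(strsplit(trimws(src$lines), "[\\s,]+", perl = TRUE))))
    values <- values[!is.na(values)]
    fid <- pair_to_complex(values, "ASCII data")
  } else {
    tab <- as.matrix(table)
    stopifnot(ncol(tab) >= 2L)
    fid <- complex(real = tab[, 1], imaginary = tab[, 2])
  }
  if (is.null(meta$dwell_s) || is.null(meta$f0_mhz) || is.null(meta$nucleus))
    stop_mrs("ASCII conversion requires dwell_s, f0_mhz and nucleus overrides",
             "mrs_metadata_error")
  img <- mrs_make_minimal(fid, dwell_s = meta$dwell_s, f0_mhz = meta$f0_mhz,
                          nucleus = meta$nucleus)
  conversion_provenance(img, "ASCII", source, meta$note)
}
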