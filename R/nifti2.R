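# Bit-exact NIfTI-2 reading and writing with the ecode-44 JSON extension.
#
# The 540-byte NIfTI-2 header is written field by field (little-endian),
# followed by the 4-byte extender, the extension records, and the complex
# data block. All sizes handled here are far below 2^31, so the int64
# header fields are written as (lo, hi) int32 pairs.

NII2_MAGIC <- as.raw(c(0x6e, 0x2b, 0x32, 0x00, 0x0d, 0x0a, 0x1a, 0x0a))

write_int64 <- function(con, v) {
  for (x in v) writeBin(c(as.integer(x), 0L), con, size = 4L, endian = "little")
}

read_int64 <- function(con, n = 1L, endian = "little") {
  vapply(seq_len(n), function(i) {
    w <- readBin(con, "integer", 2L, size = 4L, endian = endian)
    lo <- if (endian == "little") w[1] else w[2]
    hi <- if (endian == "little") w[2] else w[1]
    if (lo < 0) lo <- lo + 2^32
    lo + hi * 2^32
  }, numeric(1))
}

write_string <- function(con, s, width) {
  b <- charToRaw(s %||% "")
  b <- b[seq_len(min(length(b), width))]
  writeBin(c(b, raw(width - length(b))), con)
}

read_string <- function(con, width) {
  b <- readBin(con, "raw", width)
  b <- b[b != as.raw(0)]
  rawToChar(b)
}

bitpix_for <- function(datatype) {
  switch(as.character(datatype), "32" = 64L, "1792" = 128L,
         stop_mrs(sprintf("unsupported datatype code %d", datatype),
                  "mrs_datatype_error"))
}

# ---- extension records --------------------------------------------------

#' Build / parse a NIfTI extension record
#'
#' NIfTI extension records consist of an 8-byte preamble (esize, ecode, both
#' int32) followed by the payload, with esize a multiple of 16 covering
#' preamble plus zero-padded payload. NIfTI-MRS uses extension code 44.
#'
#' @param ext an `mrs_extension`.
#' @return `serialize_extension()`: list with `esize`, `ecode` (44), and
#'   `payload` (raw, already padded to `esize - 8`).
#' @export
serialize_extension <- function(ext) {
  payload <- charToRaw(enc2utf8(mrs_serialize_extension(ext)))
  esize <- as.integer(16 * ceiling((8 + length(payload)) / 16))
  list(esize = esize, ecode = MRS_ECODE,
       payload = c(payload, raw(esize - 8L - length(payload))))
}

#' @rdname serialize_extension
#' @param record list with `ecode` and `payload` (raw) as returned by
#'   `serialize_extension()` or read from file.
#' @export
parse_extension <- function(record) {
  if (record$ecode != MRS_ECODE)
    stop_mrs(sprintf("extension code %d is not the NIfTI-MRS code %d",
                     record$ecode, MRS_ECODE), "mrs_wrong_extension_error")
  mrs_parse_extension(rawToChar(strip_padding(record$payload)))
}

# strip trailing NUL padding from a raw payload
strip_padding <- function(payload) {
  nz <- which(payload != as.raw(0))
  if (length(nz) == 0L) raw(0) else payload[seq_len(max(nz))]
}

# ---- writing ------------------------------------------------------------

#' Write an MRS image to a NIfTI-MRS file
#'
#' Emits a NIfTI-2 file (gzip-compressed when the path ends in `.gz`)
#' carrying exactly one JSON header extension with code 44. The image must
#' pass [mrs_validate()]; `force = TRUE` writes a non-conformant file with a
#' warning instead. Reading back reproduces the data bit-exactly in the
#' declared datatype and an extension that is JSON-equal.
#'
#' @param image an `mrs_image`.
#' @param path output path, `.nii` or `.nii.gz`.
#' @param force write even if validation fails.
#' @return `path`, invisibly.
#' @export
write_mrs <- function(image, path, force = FALSE) {
  stopifnot(inherits(image, "mrs_image"))
  report <- mrs_validate(image)
  if (!report$conformant) {
    if (!force)
      stop_mrs(paste0("image is not conformant (",
                      paste(report_codes(report), collapse = ", "),
                      "); use force = TRUE to write anyway"),
               "mrs_conformance_error")
    warning("writing non-conformant file: ",
            paste(report_codes(report), collapse = ", "))
  }
  hdr <- image$header
  rec <- serialize_extension(image$extension)
  extra <- image$extra_extensions %||% list()
  extra_recs <- lapply(extra, function(e) {
    esize <- as.integer(16 * ceiling((8 + length(e$payload)) / 16))
    list(esize = esize, ecode = as.integer(e$ecode),
         payload = c(e$payload, raw(esize - 8L - length(e$payload))))
  })
  recs <- c(list(rec), extra_recs)
  vox_offset <- 544 + sum(vapply(recs, `[[`, integer(1), "esize"))

  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(540L, con, size = 4L, endian = "little")
  writeBin(NII2_MAGIC, con)
  writeBin(as.integer(hdr$datatype), con, size = 2L, endian = "little")
  writeBin(bitpix_for(hdr$datatype), con, size = 2L, endian = "little")
  write_int64(con, hdr$dim[1:8])
  writeBin(rep(0, 3), con, size = 8L, endian = "little")          # intent_p1..3
  writeBin(as.numeric(hdr$pixdim[1:8]), con, size = 8L, endian = "little")
  write_int64(con, vox_offset)
  writeBin(c(1, 0, 0, 0), con, size = 8L, endian = "little")      # scl_slope/inter, cal_max/min
  writeBin(c(0, 0), con, size = 8L, endian = "little")            # slice_duration, toffset
  write_int64(con, c(0, 0))                                       # slice_start/end
  write_string(con, hdr$descrip, 80L)
  write_string(con, "", 24L)                                      # aux_file
  writeBin(as.integer(c(hdr$qform_code, hdr$sform_code)), con, size = 4L,
           endian = "little")
  writeBin(as.numeric(c(hdr$quatern, hdr$qoffset)), con, size = 8L,
           endian = "little")
  writeBin(as.numeric(t(hdr$srow)), con, size = 8L, endian = "little")
  writeBin(c(0L, as.integer(hdr$xyzt_units), 0L), con, size = 4L,
           endian = "little")                                     # slice_code, xyzt, intent_code
  write_string(con, hdr$intent_name, 16L)
  writeBin(raw(16L), con)                                         # dim_info + unused_str
  writeBin(as.raw(c(1L, 0L, 0L, 0L)), con)                        # extender: has extensions
  for (r in recs) {
    writeBin(c(r$esize, r$ecode), con, size = 4L, endian = "little")
    writeBin(r$payload, con)
  }
  v <- as.complex(image$data)
  interleaved <- as.numeric(rbind(Re(v), Im(v)))
  writeBin(interleaved, con, size = bitpix_for(hdr$datatype) / 16L,
           endian = "little")

  bytes <- rawConnectionValue(con)
  out <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  writeBin(bytes, out)
  close(out)
  invisible(path)
}

# ---- reading ------------------------------------------------------------

read_all_bytes <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 2L)
  close(con); on.exit()
  if (length(head) == 2L && head[1] == as.raw(0x1f) && head[2] == as.raw(0x8b)) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    chunks <- list()
    repeat {
      b <- readBin(con, "raw", 2^20)
      if (length(b) == 0L) break
      chunks[[length(chunks) + 1L]] <- b
    }
    return(do.call(c, chunks))
  }
  readBin(path, "raw", file.size(path))
}

#' Read a NIfTI-MRS file
#'
#' Accepts `.nii` and `.nii.gz`. The file must be a NIfTI-2 (or, with a
#' warning, NIfTI-1) file carrying exactly one extension record with the
#' NIfTI-MRS code 44; plain structural NIfTI without that extension is
#' rejected with a pointed error. Extension records with other codes are
#' kept and re-emitted by [write_mrs()].
#'
#' @param path input path.
#' @return An `mrs_image`.
#' @export
read_mrs <- function(path) {
  bytes <- read_all_bytes(path)
  con <- rawConnection(bytes, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- "little"
  if (!sizeof_hdr %in% c(348L, 540L)) {
    sz_big <- readBin(rev(bytes[1:4]), "integer", 1L, size = 4L)
    if (sz_big %in% c(348L, 540L)) {
      endian <- "big"
      sizeof_hdr <- sz_big
    } else {
      stop_mrs("not a NIfTI file (unrecognized header size)", "mrs_io_error")
    }
  }
  parsed <- if (sizeof_hdr == 540L) read_nifti2_header(con, endian)
            else {
              warning("NIfTI-1 NIfTI-MRS file; it will be upgraded to NIfTI-2 on write")
              read_nifti1_header(con, endian)
            }
  hdr <- parsed$header
  vox_offset <- parsed$vox_offset

  # extension records
  ext_flag <- readBin(con, "raw", 4L)
  records <- list()
  if (length(ext_flag) == 4L && ext_flag[1] != as.raw(0)) {
    while (seek(con, where = NA) + 8 <= vox_offset) {
      esize <- readBin(con, "integer", 1L, size = 4L, endian = endian)
      ecode <- readBin(con, "integer", 1L, size = 4L, endian = endian)
      if (length(esize) == 0L || esize < 8L) break
      payload <- readBin(con, "raw", esize - 8L)
      records[[length(records) + 1L]] <- list(esize = esize, ecode = ecode,
                                              payload = payload)
    }
  }
  is_mrs <- vapply(records, function(r) r$ecode == MRS_ECODE, logical(1))
  if (sum(is_mrs) == 0L)
    stop_mrs(paste("no NIfTI-MRS header extension (code 44) found:",
                   "this looks like a plain NIfTI file, not NIfTI-MRS"),
             "mrs_not_mrs_error")
  if (sum(is_mrs) > 1L)
    stop_mrs("multiple code-44 extension records: metadata is ambiguous",
             "mrs_ambiguous_extension_error")
  mrs_rec <- records[[which(is_mrs)]]
  mrs_rec$payload <- strip_padding(mrs_rec$payload)
  extension <- parse_extension(mrs_rec)

  # data block
  seek(con, where = vox_offset)
  rank <- hdr$dim[1]
  np <- prod(pmax(hdr$dim[1 + seq_len(rank)], 1L))
  comp_size <- bitpix_for(hdr$datatype) / 16L
  vals <- readBin(con, "double", 2L * np, size = comp_size, endian = endian)
  if (length(vals) < 2L * np)
    stop_mrs("data block truncated", "mrs_io_error")
  data <- complex(real = vals[c(TRUE, FALSE)], imaginary = vals[c(FALSE, TRUE)])
  dim(data) <- pmax(hdr$dim[1 + seq_len(rank)], 1L)

  img <- mrs_image(data, extension, header = hdr)
  extra <- records[!is_mrs]
  if (length(extra) > 0L)
    img$extra_extensions <- lapply(extra, function(r)
      list(ecode = r$ecode, payload = r$payload))
  img
}

read_nifti2_header <- function(con, endian) {
  hdr <- default_header()
  magic <- readBin(con, "raw", 8L)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  bitpix <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  hdr$dim <- as.integer(read_int64(con, 8L, endian))
  readBin(con, "double", 3L, size = 8L, endian = endian)     # intent_p
  hdr$pixdim <- readBin(con, "double", 8L, size = 8L, endian = endian)
  vox_offset <- read_int64(con, 1L, endian)
  readBin(con, "double", 6L, size = 8L, endian = endian)     # scl/cal/slice_dur/toffset
  read_int64(con, 2L, endian)                                # slice_start/end
  hdr$descrip <- read_string(con, 80L)
  read_string(con, 24L)
  codes <- readBin(con, "integer", 2L, size = 4L, endian = endian)
  hdr$qform_code <- codes[1]; hdr$sform_code <- codes[2]
  qq <- readBin(con, "double", 6L, size = 8L, endian = endian)
  hdr$quatern <- c(b = qq[1], c = qq[2], d = qq[3])
  hdr$qoffset <- c(x = qq[4], y = qq[5], z = qq[6])
  hdr$srow <- matrix(readBin(con, "double", 12L, size = 8L, endian = endian),
                     nrow = 3L, byrow = TRUE)
  ints <- readBin(con, "integer", 3L, size = 4L, endian = endian)
  hdr$xyzt_units <- ints[2]
  hdr$intent_name <- read_string(con, 16L)
  readBin(con, "raw", 16L)                                   # dim_info + unused
  hdr$datatype <- as.integer(datatype)
  list(header = hdr, vox_offset = vox_offset)
}

read_nifti1_header <- function(con, endian) {
  hdr <- default_header()
  readBin(con, "raw", 36L)                                   # data_type..dim_info (junk)
  hdr$dim <- as.integer(readBin(con, "integer", 8L, size = 2L, endian = endian))
  readBin(con, "double", 3L, size = 4L, endian = endian)     # intent_p (float)
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # intent_code
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 2L, size = 2L, endian = endian)    # bitpix, slice_start
  hdr$pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  readBin(con, "double", 2L, size = 4L, endian = endian)     # scl_slope, scl_inter
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # slice_end
  readBin(con, "raw", 1L)                                    # slice_code
  hdr$xyzt_units <- as.integer(readBin(con, "raw", 1L))
  readBin(con, "double", 4L, size = 4L, endian = endian)     # cal_max/min, slice_dur, toffset
  readBin(con, "integer", 2L, size = 4L, endian = endian)    # glmax/glmin
  hdr$descrip <- read_string(con, 80L)
  read_string(con, 24L)
  codes <- readBin(con, "integer", 2L, size = 2L, endian = endian)
  hdr$qform_code <- codes[1]; hdr$sform_code <- codes[2]
  qq <- readBin(con, "double", 6L, size = 4L, endian = endian)
  hdr$quatern <- c(b = qq[1], c = qq[2], d = qq[3])
  hdr$qoffset <- c(x = qq[4], y = qq[5], z = qq[6])
  hdr$srow <- matrix(readBin(con, "double", 12L, size = 4L, endian = endian),
                     nrow = 3L, byrow = TRUE)
  hdr$intent_name <- read_string(con, 16L)
  readBin(con, "raw", 4L)                                    # magic
  hdr$datatype <- as.integer(datatype)
  list(header = hdr, vox_offset = vox_offset)
}
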