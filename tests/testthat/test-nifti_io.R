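# Bit-exact NIfTI-2 I/O with the code-44 JSON extension.

raw_uint16le <- function(bytes, offset) {
  as.integer(bytes[offset + 1]) + 256L * as.integer(bytes[offset + 2])
}

read_file_bytes <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 10 * 1024^2)
  } else readBin(path, "raw", file.size(path))
}

test_that("extension records follow the esize rule", {
  # payload engineered to exactly 100 bytes: esize = ceil(108/16)*16 = 112
  base <- mrs_extension(123.2, "1H")
  pad_to <- function(target) {
    n0 <- nchar(mrs_serialize_extension(mrs_extension(123.2, "1H",
             user_keys = list(p = ""))))
    mrs_extension(123.2, "1H",
                  user_keys = list(p = strrep("x", target - n0)))
  }
  ext100 <- pad_to(100)
  expect_equal(nchar(mrs_serialize_extension(ext100)), 100)
  rec <- serialize_extension(ext100)
  expect_equal(rec$esize, 112L)
  expect_equal(rec$ecode, 44L)
  # general rule over varying payload sizes
  for (k in c(0, 3, 8, 17)) {
    r <- serialize_extension(pad_to(100 + k))
    expect_equal(r$esize %% 16L, 0L)
    expect_gte(r$esize, 8L + 100L + k)
    expect_lt(r$esize, 8L + 100L + k + 16L)
  }
})

test_that("parse_extension strips padding, rejects wrong codes and bad JSON", {
  rec <- serialize_extension(random_extension())
  expect_true(any(rec$payload == as.raw(0)) || (rec$esize - 8L) == sum(rec$payload != 0))
  back <- parse_extension(rec)
  expect_identical(mrs_serialize_extension(back),
                   mrs_serialize_extension(parse_extension(rec)))
  expect_error(parse_extension(list(ecode = 6L, payload = rec$payload)),
               class = "mrs_wrong_extension_error")
  truncated <- list(ecode = 44L, payload = rec$payload[1:10])
  expect_error(parse_extension(truncated), class = "mrs_parse_error")
})

test_that("written files carry the standard's constants in their raw bytes", {
  img <- mrs_make_minimal(as_complex64(random_fid(128)), 5e-4, 123.2, "1H")
  f <- withr::local_tempfile(fileext = ".nii")
  write_mrs(img, f)
  bytes <- read_file_bytes(f)
  expect_identical(readBin(bytes[1:4], "integer", 1, 4, endian = "little"), 540L)
  expect_identical(bytes[5:8], as.raw(c(0x6e, 0x2b, 0x32, 0x00)))  # "n+2\0"
  expect_identical(raw_uint16le(bytes, 12), 32L)                   # DT_COMPLEX64
  ecode <- readBin(bytes[549:552], "integer", 1, 4, endian = "little")
  expect_identical(ecode, 44L)
  intent <- rawToChar(bytes[509:524][bytes[509:524] != as.raw(0)])
  expect_identical(intent, "mrs_v0_6")
})

test_that("write/read round trips are bit-exact over a randomized sweep", {
  set.seed(31)
  for (i in 1:16) {
    precision <- sample(c("single", "double"), 1)
    img <- random_image(rank = sample(4:7, 1), precision = precision)
    img <- mrs_edit_key(img, "EchoTime", round(runif(1, 0.01, 0.1), 5))
    f <- withr::local_tempfile(fileext = sample(c(".nii", ".nii.gz"), 1))
    write_mrs(img, f)
    back <- read_mrs(f)
    expect_identical(as.complex(back$data), as.complex(img$data))
    expect_identical(mrs_serialize_extension(back$extension),
                     mrs_serialize_extension(img$extension))
    expect_identical(back$header$dim, img$header$dim)
    expect_identical(back$header$pixdim, img$header$pixdim)
    expect_identical(back$header$datatype, img$header$datatype)
    expect_identical(back$header$intent_name, img$header$intent_name)
  }
})

test_that("written files are readable by an independent NIfTI-2 reader", {
  skip_if_not_installed("RNifti")
  img <- gen_example("svs_raw")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_mrs(img, f)
  ext_img <- RNifti::readNifti(f)
  h <- RNifti::niftiHeader(ext_img)
  expect_equal(h$dim, img$header$dim)
  # pixdim[0] (qfac) and trailing entries are normalized by RNifti; the
  # voxel sizes and dwell time must agree exactly
  expect_equal(h$pixdim[2:6], img$header$pixdim[2:6], tolerance = 1e-12)
  expect_identical(h$intent_name, "mrs_v0_6")
  expect_equal(as.complex(ext_img), as.complex(as_complex64(img$data)),
               tolerance = 1e-12, ignore_attr = TRUE)
  payload <- RNifti::extension(ext_img, 44L, "raw")
  expect_identical(jsonlite::fromJSON(rawToChar(payload[payload != as.raw(0)]),
                                      simplifyVector = FALSE)$ResonantNucleus[[1]],
                   "1H")
})

test_that("plain structural NIfTI is rejected with a pointed error", {
  skip_if_not_installed("RNifti")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, dim = c(2, 2, 2))), f)
  # (suppress the NIfTI-1 upgrade notice; the point is the missing extension)
  suppressWarnings(expect_error(read_mrs(f), class = "mrs_not_mrs_error"))
})

test_that("duplicate code-44 records are ambiguous; other codes survive rewrite", {
  img <- mrs_make_minimal(as_complex64(random_fid(64)), 5e-4, 123.2, "1H")
  f <- withr::local_tempfile(fileext = ".nii")
  img$extra_extensions <- list(list(ecode = 44L,
                                    payload = charToRaw('{"SpectrometerFrequency":[1],"ResonantNucleus":["1H"]}')))
  write_mrs(img, f)
  expect_error(read_mrs(f), class = "mrs_ambiguous_extension_error")

  img$extra_extensions <- list(list(ecode = 6L, payload = charToRaw("comment")))
  write_mrs(img, f)
  back <- read_mrs(f)
  expect_length(back$extra_extensions, 1)
  expect_equal(back$extra_extensions[[1]]$ecode, 6L)
  f2 <- withr::local_tempfile(fileext = ".nii")
  write_mrs(back, f2)
  back2 <- read_mrs(f2)
  expect_identical(mrsnifti:::strip_padding(back2$extra_extensions[[1]]$payload),
                   charToRaw("comment"))
})

test_that("non-conformant images are refused unless forced", {
  img <- mrs_make_minimal(random_fid(32), 5e-4, 123.2, "1H")
  img$header$intent_name <- "wrong"
  f <- withr::local_tempfile(fileext = ".nii")
  expect_error(write_mrs(img, f), class = "mrs_conformance_error")
  expect_warning(write_mrs(img, f, force = TRUE), "non-conformant")
  expect_identical(read_mrs(f)$header$intent_name, "wrong")
})

test_that("single-precision storage quantizes exactly as float32", {
  fid <- random_fid(64)   # doubles, generally not float32-representable
  img <- mrs_make_minimal(fid, 5e-4, 123.2, "1H", precision = "single")
  f <- withr::local_tempfile(fileext = ".nii")
  write_mrs(img, f)
  back <- read_mrs(f)
  expect_identical(as.complex(back$data), as.complex(as_complex64(fid)))
  expect_false(identical(as.complex(back$data), fid))   # rounding did occur
})
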