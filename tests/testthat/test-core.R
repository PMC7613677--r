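# Domain model and conformance validator.

test_that("a minimal single-voxel image is conformant", {
  img <- mrs_make_minimal(random_fid(512), dwell_s = 5e-4, f0_mhz = 123.2,
                          nucleus = "1H")
  expect_equal(img$header$dim, c(4L, 1L, 1L, 1L, 512L, 1L, 1L, 1L))
  expect_equal(img$header$pixdim[5], 5e-4)
  expect_equal(img$header$qform_code, 0L)
  report <- mrs_validate(img)
  expect_true(report$conformant)
  expect_length(mrsnifti:::report_codes(report), 0)
})

test_that("make_minimal encodes the implemented standard version", {
  img <- mrs_make_minimal(random_fid(64), 5e-4, 123.2, "1H")
  expect_identical(img$header$intent_name, "mrs_v0_6")
})

test_that("used dynamic dims default to the standard's purposes", {
  img <- mrs_make_minimal(array(random_fid(512 * 8), dim = c(1, 1, 1, 512, 8)),
                          5e-4, 123.2, "1H")
  expect_identical(img$extension$dim_tags[["5"]], "DIM_COIL")
  img3 <- mrs_make_minimal(array(random_fid(64 * 2 * 3 * 2),
                                 dim = c(1, 1, 1, 64, 2, 3, 2)),
                           5e-4, 123.2, "1H")
  expect_identical(img3$extension$dim_tags[["6"]], "DIM_DYN")
  expect_identical(img3$extension$dim_tags[["7"]], "DIM_INDIRECT")
})

test_that("rank 1-3 inputs gain leading singleton spatial dims", {
  img <- mrs_make_minimal(matrix(random_fid(64 * 4), 64, 4), 5e-4, 123.2, "1H")
  expect_equal(img$header$dim[1], 5L)
  expect_equal(img$header$dim[2:6], c(1L, 1L, 1L, 64L, 4L))
  expect_true(mrs_validate(img)$conformant)
})

test_that("empty FIDs are refused", {
  expect_error(mrs_make_minimal(complex(0), 5e-4, 123.2, "1H"),
               class = "mrs_empty_error")
  expect_error(mrs_make_minimal(random_fid(8), 0, 123.2, "1H"),
               class = "mrs_dwell_error")
})

test_that("an untagged used dimension is the only defect flagged", {
  data <- array(random_fid(512 * 4), dim = c(1, 1, 1, 512, 4))
  ext <- mrs_extension(123.2, "1H")   # deliberately no dim_5
  img <- mrs_image(data, ext, dwell_s = 5e-4)
  report <- mrs_validate(img)
  expect_false(report$conformant)
  expect_identical(mrsnifti:::report_codes(report), "MISSING_DIM_TAG")
})

test_that("real-valued datatype codes are non-conformant", {
  img <- mrs_make_minimal(random_fid(64), 5e-4, 123.2, "1H")
  img$header$datatype <- 16L   # DT_FLOAT32
  expect_identical(mrsnifti:::report_codes(mrs_validate(img)),
                   "NON_COMPLEX_DATATYPE")
})

test_that("ranks 4-7 validate and rank 8 is rejected", {
  for (rank in 4:8) {
    sizes <- c(1L, 1L, 1L, 32L, rep(2L, rank - 4L))
    data <- array(random_fid(prod(sizes)), dim = sizes)
    tags <- list()
    for (n in intersect(5:7, seq_len(rank))) tags[[as.character(n)]] <- "DIM_MEAS"
    ext <- mrs_extension(123.2, "1H", dim_tags = tags)
    img <- mrs_image(data, ext, dwell_s = 5e-4,
                     header = list(dim = c(rank, sizes, rep(1L, max(0L, 7L - length(sizes))))[1:8]))
    report <- mrs_validate(img)
    if (rank <= 7L) {
      expect_true(report$conformant, info = paste("rank", rank))
    } else {
      expect_true("RANK_OUT_OF_RANGE" %in% mrsnifti:::report_codes(report))
    }
  }
})

test_that("each conformance rule is individually load-bearing", {
  base <- function() {
    img <- mrs_make_minimal(array(random_fid(64 * 2), dim = c(1, 1, 1, 64, 2)),
                            5e-4, 123.2, "1H")
    expect_true(mrs_validate(img)$conformant)
    img
  }
  img <- base(); img$extension$spectrometer_frequency <- numeric(0)
  expect_identical(mrsnifti:::report_codes(mrs_validate(img)), "MISSING_MANDATORY_KEY")
  img <- base(); img$extension$resonant_nucleus <- character(0)
  expect_identical(mrsnifti:::report_codes(mrs_validate(img)), "MISSING_MANDATORY_KEY")
  img <- base(); img$extension$dim_tags[["5"]] <- NULL
  expect_identical(mrsnifti:::report_codes(mrs_validate(img)), "MISSING_DIM_TAG")
  img <- base(); img$header$datatype <- 64L
  expect_identical(mrsnifti:::report_codes(mrs_validate(img)), "NON_COMPLEX_DATATYPE")
  img <- base(); img$header$pixdim[5] <- -1
  expect_identical(mrsnifti:::report_codes(mrs_validate(img)), "NONPOSITIVE_DWELL")
  img <- base(); img$header$intent_name <- "mrs_0.6"
  expect_identical(mrsnifti:::report_codes(mrs_validate(img)), "BAD_INTENT_NAME")
})

test_that("a version ahead of the implementation warns but conforms", {
  img <- mrs_make_minimal(random_fid(32), 5e-4, 123.2, "1H")
  img$header$intent_name <- "mrs_v9_0"
  report <- mrs_validate(img)
  expect_true(report$conformant)
  expect_identical(mrsnifti:::report_codes(report, "warning"), "VERSION_AHEAD")
})

test_that("an invalid quaternion norm is flagged", {
  img <- mrs_make_minimal(random_fid(32), 5e-4, 123.2, "1H",
                          geometry = diag(c(10, 10, 10, 1)))
  img$header$quatern <- c(b = 0.9, c = 0.9, d = 0.9)
  expect_true("BAD_QUATERNION" %in% mrsnifti:::report_codes(mrs_validate(img)))
})

test_that("classify_key is total over exactly four categories", {
  expect_identical(classify_key("ResonantNucleus"), "mandatory")
  expect_identical(classify_key("SpectrometerFrequency"), "mandatory")
  expect_identical(classify_key("dim_6_info"), "dimension")
  expect_identical(classify_key("dim_5"), "dimension")
  expect_identical(classify_key("dim_7_header"), "dimension")
  expect_identical(classify_key("EchoTime"), "standard")
  expect_identical(classify_key("MySiteNotes"), "user")
  expect_identical(classify_key("dim_4"), "user")   # only 5-7 are dimension keys
  set.seed(7)
  pool <- c(key_registry()$name, mrsnifti:::MANDATORY_KEYS,
            paste0("dim_", 5:7), paste0("dim_", 5:7, "_info"),
            replicate(50, paste(sample(c(letters, LETTERS), 8), collapse = "")))
  cats <- classify_key(pool)
  expect_true(all(cats %in% c("mandatory", "dimension", "standard", "user")))
  expect_setequal(unique(cats), c("mandatory", "dimension", "standard", "user"))
})

test_that("randomized shapes from make_minimal always validate", {
  set.seed(11)
  for (i in 1:25) {
    img <- random_image(rank = sample(4:7, 1),
                        precision = sample(c("single", "double"), 1))
    expect_true(mrs_validate(img)$conformant)
  }
})
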