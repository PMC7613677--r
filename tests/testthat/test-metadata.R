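# Key registry, dynamic headers, provenance, editing, anonymization.

test_that("registry lookups match an independent parse of the bundled table", {
  tab <- read.delim(system.file("extdata", "standard_keys.tsv",
                                package = "mrsnifti"), quote = "")
  expect_false(anyDuplicated(tab$name) > 0)
  # minimum coverage: acquisition, hardware and subject keys
  expect_true(all(c("EchoTime", "RepetitionTime", "InversionTime",
                    "SequenceName", "TxOffset",
                    "Manufacturer", "ManufacturersModelName",
                    "DeviceSerialNumber", "SoftwareVersions",
                    "PatientName", "PatientID", "PatientDoB", "PatientSex",
                    "PatientWeight") %in% tab$name))
  for (i in seq_len(nrow(tab))) {
    def <- key_definition(tab$name[i])
    expect_identical(def$value_type, tab$value_type[i])
    expect_identical(def$private, as.logical(tab$private[i]))
  }
  et <- key_definition("EchoTime")
  expect_identical(et$value_type, "number")
  expect_identical(et$units, "s")
  expect_false(et$private)
  expect_true(key_definition("PatientName")$private)
  expect_null(key_definition("NotAKey"))
  # subject-identifying keys are all privacy-flagged
  subject <- tab$name[startsWith(tab$name, "Patient") &
                        tab$name != "PatientPosition"]
  expect_true(all(vapply(subject, function(k) key_definition(k)$private,
                         logical(1))))
})

test_that("is_private honours both the registry flag and the prefix rule", {
  expect_true(is_private("private_notes"))
  expect_true(is_private("PatientDoB"))
  expect_false(is_private("SpectrometerFrequency"))
  expect_false(is_private("ResonantNucleus"))
  expect_false(is_private("EchoTime"))
  expect_false(is_private("somethingelse"))
})

test_that("anonymize removes nested private keys and keeps the rest", {
  ext <- mrs_extension(123.2, "1H",
                       user_keys = list(Custom = list(private_id = "X", field = 1L)))
  res <- mrs_anonymize(ext)
  expect_identical(res$removed, "Custom.private_id")
  expect_identical(res$image$user_keys$Custom, list(field = 1L))
})

test_that("anonymize deletes privacy-flagged standard keys", {
  ext <- mrs_extension(123.2, "1H",
                       standard_keys = list(PatientName = "DOE", EchoTime = 0.03))
  res <- mrs_anonymize(ext)
  expect_identical(res$removed, "PatientName")
  expect_identical(names(res$image$standard_keys), "EchoTime")
})

test_that("anonymize is idempotent and leaves clean files untouched", {
  ext <- random_extension(with_private = FALSE)
  res <- mrs_anonymize(ext)
  expect_length(res$removed, 0)
  expect_identical(mrs_serialize_extension(res$image),
                   mrs_serialize_extension(ext))
  dirty <- random_extension(with_private = TRUE)
  once <- mrs_anonymize(dirty)$image
  twice <- mrs_anonymize(once)$image
  expect_identical(mrs_serialize_extension(once), mrs_serialize_extension(twice))
})

test_that("a brute-force scan finds nothing private after anonymize", {
  set.seed(3)
  for (i in 1:20) {
    ext <- random_extension()
    ext$user_keys[[paste0("private_", i)]] <- list(x = i)
    ext$user_keys$Wrapper <- list(inner = list(PatientID = "p", ok = i))
    expect_gt(length(scan_private_keys(ext)), 0)
    clean <- mrs_anonymize(ext)$image
    expect_length(scan_private_keys(clean), 0)
  }
})

test_that("anonymize preserves the data array bit-for-bit and conformance", {
  img <- gen_example("mrsi_proc")
  res <- mrs_anonymize(img)
  expect_identical(res$image$data, img$data)
  expect_true(all(c("PatientName", "PatientID", "PatientDoB") %in% res$removed))
  expect_true(mrs_validate(res$image)$conformant)
})

test_that("anonymize refuses to remove mandatory keys via extra_keys", {
  expect_error(mrs_anonymize(random_extension(), extra_keys = "ResonantNucleus"),
               class = "mrs_mandatory_error")
  res <- mrs_anonymize(random_extension(), extra_keys = "Manufacturer")
  expect_true("Manufacturer" %in% res$removed)
})

test_that("set_dim_tag enforces vocabulary and header lengths", {
  data5 <- array(random_fid(64 * 4), dim = c(1, 1, 1, 64, 4))
  img <- mrs_make_minimal(data5, 5e-4, 123.2, "1H")
  img <- set_dim_tag(img, 5, "DIM_COIL")
  expect_true(mrs_validate(img)$conformant)
  expect_error(set_dim_tag(img, 5, "DIM_BANANA"), class = "mrs_tag_error")
  expect_error(set_dim_tag(img, 7, "DIM_EDIT"), class = "mrs_rank_error")

  data7 <- array(random_fid(64 * 2), dim = c(1, 1, 1, 64, 1, 1, 2))
  img7 <- mrs_make_minimal(data7, 5e-4, 123.2, "1H",
                           dim_tags = list("7" = "DIM_EDIT"))
  img7 <- set_dim_tag(img7, 7, "DIM_EDIT",
                      header = list(EditCondition = c("ON", "OFF")))
  expect_true(mrs_validate(img7)$conformant)
  expect_error(set_dim_tag(img7, 7, "DIM_EDIT",
                           header = list(EditCondition = c("A", "B", "C"))),
               class = "mrs_shape_error")
})

test_that("a size-1 tagged dimension is legal and the tag is retained", {
  data <- array(random_fid(64), dim = c(1, 1, 1, 64, 1))
  img <- mrs_make_minimal(data, 5e-4, 123.2, "1H",
                          dim_tags = list("5" = "DIM_DYN"))
  expect_true(mrs_validate(img)$conformant)
  expect_identical(img$extension$dim_tags[["5"]], "DIM_DYN")
})

test_that("dynamic header values resolve across long, compact and wrapped forms", {
  ext <- mrs_extension(123.2, "1H",
    dim_tags = list("5" = "DIM_USER_0"),
    dim_headers = list("5" = list(
      EchoTime = c(0.01, 0.02, 0.03),
      Compact = list(start = 0.01, increment = 0.01),
      Wrapped = list(Value = list(start = 5, increment = 2),
                     Description = "arbitrary"))))
  expect_equal(get_dim_header_value(ext, 5, "EchoTime", 2), 0.03)
  expect_equal(get_dim_header_value(ext, 5, "Compact", 2), 0.03)
  # compact form must agree with its long-form expansion at every index
  for (i in 0:4)
    expect_equal(get_dim_header_value(ext, 5, "Wrapped", i), 5 + 2 * i)
  expect_error(get_dim_header_value(ext, 5, "TR", 0), class = "mrs_lookup_error")
  expect_error(get_dim_header_value(ext, 5, "EchoTime", 3), class = "mrs_bounds_error")
  expect_error(get_dim_header_value(ext, 5, "EchoTime", -1), class = "mrs_bounds_error")
})

test_that("provenance entries append sequentially and are checked", {
  ext <- mrs_extension(123.2, "1H")
  expect_length(ext$processing_applied, 0)
  ext <- append_provenance(ext, provenance_entry("a", "p", "1"))
  expect_length(ext$processing_applied, 1)
  ext <- append_provenance(ext, provenance_entry("b", "q", "2"))
  expect_identical(vapply(ext$processing_applied, `[[`, "", "Method"),
                   c("a", "b"))
  expect_error(provenance_entry("a", "", "1"), class = "mrs_provenance_error")
  expect_error(append_provenance(ext, list(Method = "x")),
               class = "mrs_provenance_error")
})

test_that("edit_key enforces registry value types; mandatory keys are fixed", {
  ext <- mrs_extension(123.2, "1H")
  ext <- mrs_edit_key(ext, "EchoTime", 0.030)
  expect_identical(ext$standard_keys$EchoTime, 0.030)
  expect_error(mrs_edit_key(ext, "EchoTime", "thirty"), class = "mrs_type_error")
  expect_error(mrs_remove_key(ext, "SpectrometerFrequency"),
               class = "mrs_mandatory_error")
  ext <- mrs_edit_key(ext, "freeform", list(a = 1))
  expect_identical(ext$user_keys$freeform, list(a = 1))
  ext <- mrs_remove_key(ext, "EchoTime")
  expect_null(ext$standard_keys$EchoTime)
})

test_that("extension JSON round-trips losslessly", {
  set.seed(5)
  for (i in 1:15) {
    ext <- random_extension(with_private = sample(c(TRUE, FALSE), 1))
    back <- mrs_parse_extension(mrs_serialize_extension(ext))
    expect_identical(mrs_serialize_extension(back), mrs_serialize_extension(ext))
    expect_equal(back$spectrometer_frequency, ext$spectrometer_frequency)
    expect_identical(back$user_keys, ext$user_keys)
  }
})
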