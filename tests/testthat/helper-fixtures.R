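# Shared fixture builders. Everything is generated in code; no binary test
# data ships with the package.

random_fid <- function(n) complex(real = rnorm(n), imaginary = rnorm(n))

# A random conformant image with the given rank; sizes kept tiny.
random_image <- function(rank = 4L, precision = "single") {
  sizes <- c(sample(1:2, 3, replace = TRUE), sample(c(16L, 32L), 1),
             sample(2:3, 3, replace = TRUE))[seq_len(rank)]
  data <- array(random_fid(prod(sizes)), dim = sizes)
  if (precision == "single") data <- as_complex64(data)
  mrs_make_minimal(data, dwell_s = runif(1, 1e-4, 1e-3),
                   f0_mhz = runif(1, 10, 300),
                   nucleus = sample(c("1H", "31P", "13C"), 1),
                   precision = precision)
}

# A random extension with nested user metadata, some of it private.
# Values avoid length-1 arrays-of-one ambiguity so JSON round trips are
# exactly invertible.
random_extension <- function(with_private = TRUE) {
  user <- list(
    Custom = list(field = runif(1), private_id = "subject-007",
                  deep = list(private_tag = "x", keepme = "y")),
    mySiteNotes = paste(sample(letters, 5), collapse = ""),
    private_batch = "batchA"
  )
  std <- list(EchoTime = round(runif(1, 0.01, 0.1), 4),
              PatientName = "DOE^JANE",
              Manufacturer = "Synthetic")
  if (!with_private) {
    user$Custom$private_id <- NULL
    user$Custom$deep$private_tag <- NULL
    user$private_batch <- NULL
    std$PatientName <- NULL
  }
  mrs_extension(
    spectrometer_frequency = round(runif(1, 10, 300), 3),
    resonant_nucleus = "1H",
    standard_keys = std, user_keys = user,
    processing_applied = list(provenance_entry("step", "prog", "1.0")))
}

# Recursive scan of a serialized extension for privacy-flagged keys: the
# brute-force oracle that anonymize() is tested against.
scan_private_keys <- function(ext) {
  jl <- jsonlite::fromJSON(mrs_serialize_extension(ext),
                           simplifyVector = FALSE)
  found <- character(0)
  walk <- function(x) {
    if (!is.list(x)) return(invisible())
    nms <- names(x)
    for (i in seq_along(x)) {
      if (!is.null(nms) && nzchar(nms[i]) && is_private(nms[i]))
        found <<- c(found, nms[i])
      walk(x[[i]])
    }
  }
  walk(jl)
  found
}

# Random rigid (rotation x scales + translation) affine.
random_rigid_affine <- function(left_handed = FALSE) {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  R <- matrix(c(
    a*a + b*b - c*c - d*d, 2*(b*c - a*d),         2*(b*d + a*c),
    2*(b*c + a*d),         a*a + c*c - b*b - d*d, 2*(c*d - a*b),
    2*(b*d - a*c),         2*(c*d + a*b),         a*a + d*d - b*b - c*c
  ), nrow = 3, byrow = TRUE)
  scales <- runif(3, 0.5, 20)
  M <- R %*% diag(scales)
  if (left_handed) M[, 3] <- -M[, 3]
  rbind(cbind(M, rnorm(3, sd = 50)), c(0, 0, 0, 1))
}

lcmodel_fixture <- function(npairs = 4, deltat = " DELTAT = 5.e-04") {
  vals <- sprintf("%.6f %.6f", seq_len(npairs) * 0.1, -seq_len(npairs) * 0.05)
  c(" $SEQPAR",
    " ECHOT = 30.00",
    " HZPPPM = 123.25",
    deltat,
    " $END",
    " $NMID",
    " ID='fixture', FMTDAT='(2E15.6)'",
    " $END",
    vals)
}

jmrui_fixture <- function(npts = 8, nsig = 1, declared = NULL) {
  set.seed(42)
  rows <- sprintf("%.5f\t%.5f", rnorm(npts * nsig), rnorm(npts * nsig))
  c("jMRUI Data Textfile", "",
    "Filename: fixture.txt", "",
    sprintf("PointsInDataset: %d", declared %||% npts),
    sprintf("DatasetsInFile: %d", nsig),
    "SamplingInterval: 0.25",
    "ZeroOrderPhase: 0",
    "TransmitterFrequency: 123250000",
    "MagneticField: 2.9",
    "TypeOfNucleus: 1H",
    "", "Signal and FFT", "Real\tImaginary", "",
    "Signal 1 out of 1 in file", rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
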