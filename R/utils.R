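# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mrs <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "mrs_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)

#' Round complex values through IEEE single precision
#'
#' Returns the value each element takes after storage as a pair of 32-bit
#' floats, i.e. the representation used by the single-precision complex
#' NIfTI datatype (code 32). Useful for predicting bit-exact round trips.
#'
#' @param x complex (or numeric) vector or array.
#' @return complex vector/array of the same shape.
#' @export
as_complex64 <- function(x) {
  d <- dim(x)
  v <- as.complex(x)
  re <- readBin(writeBin(Re(v), raw(), size = 4L), "double", length(v), size = 4L)
  im <- readBin(writeBin(Im(v), raw(), size = 4L), "double", length(v), size = 4L)
  out <- complex(real = re, imaginary = im)
  dim(out) <- d
  out
}

# Run code with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards (so simulation never perturbs user code).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Dimension sizes of the data array padded to length 7 with trailing 1s.
dims7 <- function(x) {
  d <- dim(x) %||% length(x)
  c(d, rep(1L, max(0L, 7L - length(d))))
}
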