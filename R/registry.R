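# Standard-defined key registry and dimension-tag vocabulary.
#
# Both are data, not code: tab-separated tables under inst/extdata/ so the
# full vocabulary from newer revisions of the standard can be dropped in
# without touching the package source.

registry_env <- new.env(parent = emptyenv())

MANDATORY_KEYS <- c("SpectrometerFrequency", "ResonantNucleus")

#' The bundled standard-key registry
#'
#' Each standard-defined metadata key carries a value type, units, a
#' privacy-sensitive flag used by [mrs_anonymize()], and a one-line
#' description.
#'
#' @return A data frame with columns `name`, `value_type`, `units`,
#'   `private`, `doc`.
#' @export
key_registry <- function() {
  if (is.null(registry_env$keys)) {
    path <- system.file("extdata", "standard_keys.tsv", package = "mrsnifti",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                             na.strings = "NA")
    stopifnot(!anyDuplicated(tab$name))
    tab$private <- as.logical(tab$private)
    registry_env$keys <- tab
  }
  registry_env$keys
}

#' The dimension-tag vocabulary
#'
#' Predefined purposes for the dynamic dimensions 5-7 (`DIM_COIL`,
#' `DIM_DYN`, ..., plus the user-defined `DIM_USER_{0-2}` slots).
#'
#' @return A data frame with columns `tag` and `doc`.
#' @export
dim_tag_vocabulary <- function() {
  if (is.null(registry_env$tags)) {
    path <- system.file("extdata", "dim_tags.tsv", package = "mrsnifti",
                        mustWork = TRUE)
    registry_env$tags <- utils::read.delim(path, stringsAsFactors = FALSE,
                                           quote = "")
  }
  registry_env$tags
}

#' Look up a standard-defined key
#'
#' @param name key name, e.g. `"EchoTime"`.
#' @return A one-row list with fields `name`, `value_type`, `units`,
#'   `private`, `doc`, or `NULL` if the key is not standard-defined.
#' @examples
#' key_definition("EchoTime")$units   # "s"
#' key_definition("NotAKey")          # NULL
#' @export
key_definition <- function(name) {
  stopifnot(is_scalar_string(name))
  reg <- key_registry()
  i <- match(name, reg$name)
  if (is.na(i)) return(NULL)
  as.list(reg[i, ])
}

#' Is a metadata key privacy-sensitive?
#'
#' A key must be removed by anonymization when it is standard-defined with
#' the privacy flag set, or when its name (at any nesting depth) starts with
#' `"private_"` — the self-marking convention for user-defined metadata.
#'
#' @param name key name.
#' @return `TRUE` or `FALSE`.
#' @export
is_private <- function(name) {
  stopifnot(is.character(name))
  def_private <- vapply(name, function(nm) {
    d <- key_definition(nm)
    !is.null(d) && isTRUE(d$private)
  }, logical(1), USE.NAMES = FALSE)
  def_private | startsWith(name, "private_")
}

#' Classify a header-extension key
#'
#' The header extension holds four kinds of metadata key: the two mandatory
#' keys, the per-dimension keys `dim_{5|6|7}` (with `_info` / `_header`
#' variants), standard-defined keys from the bundled registry, and
#' user-defined keys (everything else).
#'
#' @param name key name(s).
#' @return character vector over `"mandatory"`, `"dimension"`, `"standard"`,
#'   `"user"`.
#' @examples
#' classify_key(c("ResonantNucleus", "dim_6_info", "EchoTime", "MySiteNotes"))
#' @export
classify_key <- function(name) {
  stopifnot(is.character(name), all(nzchar(name)))
  vapply(name, function(nm) {
    if (nm %in% MANDATORY_KEYS) return("mandatory")
    if (grepl("^dim_[567](_info|_header)?$", nm)) return("dimension")
    if (!is.null(key_definition(nm))) return("standard")
    "user"
  }, character(1), USE.NAMES = FALSE)
}

# Valid dim_{n} tag strings.
valid_dim_tags <- function() dim_tag_vocabulary()$tag

# Expected R type check for a registry value_type.
check_value_type <- function(value, value_type) {
  switch(value_type,
    "number" = is_scalar_number(value),
    "string" = is_scalar_string(value),
    "number-array" = is.numeric(value) && length(value) >= 1L,
    "string-array" = is.character(value) && length(value) >= 1L,
    "bool" = is.logical(value) && length(value) == 1L && !is.na(value),
    "object" = is.list(value),
    TRUE
  )
}
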