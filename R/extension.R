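# Header-extension model: the JSON metadata block of a NIfTI-MRS file.
#
# An `mrs_extension` keeps the four key categories apart (mandatory,
# dimension, standard-defined, user-defined) plus processing provenance.
# Serialization emits keys in a stable order (mandatory, dim_*, standard,
# user, ProcessingApplied) so written files are diffable; readers must not
# rely on that order.

#' Construct a header extension
#'
#' @param spectrometer_frequency numeric vector, MHz; one value per nucleus.
#' @param resonant_nucleus character vector, e.g. `"1H"`, `"31P"`.
#' @param dim_tags named list/character, names in `c("5","6","7")`, values
#'   from [dim_tag_vocabulary()].
#' @param dim_infos named list of free-text descriptions for `DIM_USER_*`
#'   dimensions.
#' @param dim_headers named list (per dimension) of per-key dynamic header
#'   specifications: either a long-form vector with one element per position
#'   along the dimension, a compact `list(start =, increment =)` pair, or
#'   either of those wrapped as `list(Value =, Description =)`.
#' @param standard_keys named list of standard-defined key values.
#' @param user_keys named list of user-defined values (arbitrary JSON).
#' @param processing_applied list of entries from [provenance_entry()].
#' @return An object of class `mrs_extension`.
#' @export
mrs_extension <- function(spectrometer_frequency, resonant_nucleus,
                          dim_tags = list(), dim_infos = list(),
                          dim_headers = list(), standard_keys = list(),
                          user_keys = list(), processing_applied = list()) {
  spectrometer_frequency <- as.numeric(spectrometer_frequency)
  resonant_nucleus <- as.character(resonant_nucleus)
  if (length(spectrometer_frequency) == 0L || any(!is.finite(spectrometer_frequency)) ||
      any(spectrometer_frequency <= 0))
    stop_mrs("SpectrometerFrequency must be a non-empty vector of positive MHz values",
             "mrs_mandatory_error")
  if (length(resonant_nucleus) == 0L || any(!nzchar(resonant_nucleus)))
    stop_mrs("ResonantNucleus must be a non-empty vector of nucleus strings",
             "mrs_mandatory_error")
  dim_tags <- lapply(dim_tags, as.character)
  for (tag in dim_tags)
    if (!tag %in% valid_dim_tags())
      stop_mrs(sprintf("unknown dimension tag '%s'", tag), "mrs_tag_error")
  structure(list(
    spectrometer_frequency = spectrometer_frequency,
    resonant_nucleus = resonant_nucleus,
    dim_tags = dim_tags,
    dim_infos = lapply(dim_infos, as.character),
    dim_headers = dim_headers,
    standard_keys = standard_keys,
    user_keys = user_keys,
    processing_applied = processing_applied
  ), class = "mrs_extension")
}

#' @export
print.mrs_extension <- function(x, ...) {
  cat(jsonlite::prettify(mrs_serialize_extension(x)))
  invisible(x)
}

#' Construct a processing-provenance entry
#'
#' Each preprocessing step applied to the data can be recorded sequentially
#' in the extension's `ProcessingApplied` field.
#'
#' @param method what was done (e.g. `"Coil combination"`).
#' @param program the program that did it.
#' @param version the program version.
#' @param details optional free-form string or object.
#' @return A named list with members `Method`, `Program`, `Version` and
#'   optionally `Details` (the on-disk member names).
#' @export
provenance_entry <- function(method, program, version, details = NULL) {
  if (!is_scalar_string(method) || !is_scalar_string(program) ||
      !is_scalar_string(version))
    stop_mrs("provenance entries need non-empty method, program and version",
             "mrs_provenance_error")
  out <- list(Method = method, Program = program, Version = version)
  if (!is.null(details)) out$Details <- details
  out
}

#' Append a provenance entry
#'
#' Entries are stored sequentially: existing entries are untouched and the
#' new entry goes last.
#'
#' @param ext an `mrs_extension` or `mrs_image`.
#' @param entry a [provenance_entry()].
#' @return The modified object (same class as `ext`).
#' @export
append_provenance <- function(ext, entry) {
  if (inherits(ext, "mrs_image")) {
    ext$extension <- append_provenance(ext$extension, entry)
    return(ext)
  }
  stopifnot(inherits(ext, "mrs_extension"))
  if (!is.list(entry) || !is_scalar_string(entry$Method %||% "") ||
      !is_scalar_string(entry$Program %||% "") ||
      !is_scalar_string(entry$Version %||% ""))
    stop_mrs("entry must carry non-empty Method, Program and Version",
             "mrs_provenance_error")
  ext$processing_applied <- c(ext$processing_applied, list(entry))
  ext
}

# ---- dynamic (per-element) header values --------------------------------

# Strip the optional {Value, Description} wrapper.
unwrap_dyn <- function(spec) {
  if (is.list(spec) && !is.null(spec$Value)) spec$Value else spec
}

is_compact_dyn <- function(spec) {
  is.list(spec) && !is.null(spec$start) && !is.null(spec$increment)
}

# Expand a dynamic-header specification to its long form (length = size).
expand_dyn <- function(spec, size) {
  v <- unwrap_dyn(spec)
  if (is_compact_dyn(v)) return(v$start + (seq_len(size) - 1) * v$increment)
  v
}

# Length of the long form, or NA for compact (any size fits).
dyn_length <- function(spec) {
  v <- unwrap_dyn(spec)
  if (is_compact_dyn(v)) NA_integer_ else length(v)
}

#' Read one element's value from a dynamic header
#'
#' `dim_{n}_header` associates each position along a dynamic dimension with
#' a metadata value, either as a long-form array or as a compact
#' `{start, increment}` arithmetic progression. The optional
#' `{Value, Description}` wrapper is unwrapped transparently.
#'
#' @param ext `mrs_extension` (or `mrs_image`).
#' @param n dimension number (5, 6 or 7).
#' @param key dynamic header key, e.g. `"EchoTime"`.
#' @param index 0-based position along the dimension, matching the on-disk
#'   indexing convention of the standard.
#' @return The value at that position.
#' @export
get_dim_header_value <- function(ext, n, key, index) {
  if (inherits(ext, "mrs_image")) ext <- ext$extension
  stopifnot(inherits(ext, "mrs_extension"), n %in% 5:7,
            is_scalar_string(key), is_scalar_number(index))
  hdr <- ext$dim_headers[[as.character(n)]]
  if (is.null(hdr) || is.null(hdr[[key]]))
    stop_mrs(sprintf("no dynamic header key '%s' on dimension %d", key, n),
             "mrs_lookup_error")
  spec <- unwrap_dyn(hdr[[key]])
  if (is_compact_dyn(spec)) {
    if (index < 0) stop_mrs("index out of range", "mrs_bounds_error")
    return(spec$start + index * spec$increment)
  }
  if (index < 0 || index >= length(spec))
    stop_mrs("index out of range", "mrs_bounds_error")
  spec[[index + 1L]]
}

# ---- key editing --------------------------------------------------------

#' Edit or remove a metadata key
#'
#' `mrs_edit_key()` sets a key's value; for standard-defined keys the value
#' is checked against the registry's value type. `mrs_remove_key()` deletes
#' a key; the two mandatory keys cannot be removed.
#'
#' @param ext `mrs_extension` or `mrs_image`.
#' @param name key name. `dim_{n}` keys are routed through the tag
#'   vocabulary check.
#' @param value new value (R representation of the JSON value).
#' @return The modified object.
#' @export
mrs_edit_key <- function(ext, name, value) {
  if (inherits(ext, "mrs_image")) {
    ext$extension <- mrs_edit_key(ext$extension, name, value)
    return(ext)
  }
  stopifnot(inherits(ext, "mrs_extension"), is_scalar_string(name))
  switch(classify_key(name),
    mandatory = {
      if (name == "SpectrometerFrequency") {
        value <- as.numeric(value)
        if (length(value) == 0L || any(value <= 0))
          stop_mrs("SpectrometerFrequency must be positive", "mrs_type_error")
        ext$spectrometer_frequency <- value
      } else {
        value <- as.character(value)
        if (length(value) == 0L || any(!nzchar(value)))
          stop_mrs("ResonantNucleus must be non-empty strings", "mrs_type_error")
        ext$resonant_nucleus <- value
      }
    },
    dimension = {
      n <- substr(name, 5, 5)
      if (grepl("_info$", name)) ext$dim_infos[[n]] <- as.character(value)
      else if (grepl("_header$", name)) ext$dim_headers[[n]] <- value
      else {
        if (!value %in% valid_dim_tags())
          stop_mrs(sprintf("unknown dimension tag '%s'", value), "mrs_tag_error")
        ext$dim_tags[[n]] <- value
      }
    },
    standard = {
      def <- key_definition(name)
      if (!check_value_type(value, def$value_type))
        stop_mrs(sprintf("value for '%s' must have type %s", name, def$value_type),
                 "mrs_type_error")
      ext$standard_keys[[name]] <- value
    },
    user = {
      ext$user_keys[[name]] <- value
    }
  )
  ext
}

#' @rdname mrs_edit_key
#' @export
mrs_remove_key <- function(ext, name) {
  if (inherits(ext, "mrs_image")) {
    ext$extension <- mrs_remove_key(ext$extension, name)
    return(ext)
  }
  stopifnot(inherits(ext, "mrs_extension"), is_scalar_string(name))
  if (name %in% MANDATORY_KEYS)
    stop_mrs(sprintf("'%s' is mandatory and cannot be removed", name),
             "mrs_mandatory_error")
  if (classify_key(name) == "dimension") {
    n <- substr(name, 5, 5)
    if (grepl("_info$", name)) ext$dim_infos[[n]] <- NULL
    else if (grepl("_header$", name)) ext$dim_headers[[n]] <- NULL
    else ext$dim_tags[[n]] <- NULL
  } else {
    ext$standard_keys[[name]] <- NULL
    ext$user_keys[[name]] <- NULL
  }
  ext
}

# ---- JSON serialization -------------------------------------------------

# Canonical JSON form: named lists recurse, atomic scalars unbox, atomic
# vectors stay arrays. Mandatory keys are forced to arrays by the caller.
canonical_json_value <- function(x) {
  if (inherits(x, "scalar")) return(x)
  if (is.list(x)) return(lapply(x, canonical_json_value))
  if (is.atomic(x) && length(x) == 1L && is.null(dim(x))) return(jsonlite::unbox(x))
  x
}

# Assemble the on-disk named list in stable key order.
ext_to_json_list <- function(ext) {
  out <- list(
    SpectrometerFrequency = I(ext$spectrometer_frequency),
    ResonantNucleus = I(ext$resonant_nucleus)
  )
  for (n in c("5", "6", "7")) {
    if (!is.null(ext$dim_tags[[n]]))
      out[[paste0("dim_", n)]] <- jsonlite::unbox(ext$dim_tags[[n]])
    if (!is.null(ext$dim_infos[[n]]))
      out[[paste0("dim_", n, "_info")]] <- jsonlite::unbox(ext$dim_infos[[n]])
    if (!is.null(ext$dim_headers[[n]]))
      out[[paste0("dim_", n, "_header")]] <- canonical_json_value(ext$dim_headers[[n]])
  }
  for (nm in names(ext$standard_keys))
    out[[nm]] <- canonical_json_value(ext$standard_keys[[nm]])
  for (nm in names(ext$user_keys))
    out[[nm]] <- canonical_json_value(ext$user_keys[[nm]])
  if (length(ext$processing_applied) > 0L)
    out$ProcessingApplied <- lapply(ext$processing_applied, canonical_json_value)
  out
}

#' Serialize / parse the header extension JSON
#'
#' `mrs_serialize_extension()` emits canonical UTF-8 JSON with keys in a
#' stable order; `mrs_parse_extension()` is its inverse and accepts keys in
#' any order, routing each by [classify_key()].
#'
#' @param ext an `mrs_extension`.
#' @return A JSON string / an `mrs_extension`.
#' @export
mrs_serialize_extension <- function(ext) {
  stopifnot(inherits(ext, "mrs_extension"))
  as.character(jsonlite::toJSON(ext_to_json_list(ext), auto_unbox = FALSE,
                                digits = I(17), null = "null"))
}

#' @rdname mrs_serialize_extension
#' @param json a JSON string (the extension payload, padding stripped).
#' @export
mrs_parse_extension <- function(json) {
  jl <- tryCatch(
    jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE),
    error = function(e) stop_mrs(paste("malformed extension JSON:",
                                       conditionMessage(e)), "mrs_parse_error"))
  if (!is.list(jl) || is.null(names(jl)))
    stop_mrs("extension payload is not a JSON object", "mrs_parse_error")
  if (is.null(jl$SpectrometerFrequency) || is.null(jl$ResonantNucleus))
    stop_mrs("extension lacks a mandatory key", "mrs_mandatory_error")
  dim_tags <- list(); dim_infos <- list(); dim_headers <- list()
  standard <- list(); user <- list()
  for (nm in names(jl)) {
    if (nm %in% c(MANDATORY_KEYS, "ProcessingApplied")) next
    cls <- classify_key(nm)
    if (cls == "dimension") {
      n <- substr(nm, 5, 5)
      if (grepl("_info$", nm)) dim_infos[[n]] <- jl[[nm]]
      else if (grepl("_header$", nm)) dim_headers[[n]] <- jl[[nm]]
      else dim_tags[[n]] <- jl[[nm]]
    } else if (cls == "standard") standard[[nm]] <- jl[[nm]]
    else user[[nm]] <- jl[[nm]]
  }
  mrs_extension(
    spectrometer_frequency = as.numeric(jl$SpectrometerFrequency),
    resonant_nucleus = as.character(jl$ResonantNucleus),
    dim_tags = dim_tags, dim_infos = dim_infos, dim_headers = dim_headers,
    standard_keys = standard, user_keys = user,
    processing_applied = jl$ProcessingApplied %||% list()
  )
}

# ---- anonymization ------------------------------------------------------

# Recursively prune privacy-sensitive (or explicitly listed) keys from a
# named-list JSON structure, collecting dotted paths of removals.
prune_private <- function(x, path, extra, top_level = FALSE) {
  if (is.list(x) && is.null(names(x))) {
    removed <- character(0)
    for (i in seq_along(x)) {
      sub <- prune_private(x[[i]], sprintf("%s[%d]", path, i - 1L), extra)
      x[[i]] <- sub$value
      removed <- c(removed, sub$removed)
    }
    return(list(value = x, removed = removed))
  }
  if (!is.list(x)) return(list(value = x, removed = character(0)))
  removed <- character(0)
  keep <- list()
  for (nm in names(x)) {
    here <- if (nzchar(path)) paste(path, nm, sep = ".") else nm
    protected <- top_level && nm %in% MANDATORY_KEYS
    if (!protected && (is_private(nm) || nm %in% extra)) {
      removed <- c(removed, here)
    } else {
      sub <- prune_private(x[[nm]], here, extra)
      keep[[nm]] <- sub$value
      removed <- c(removed, sub$removed)
    }
  }
  list(value = keep, removed = removed)
}

#' Remove protected health information from the metadata
#'
#' Deletes every metadata key, at any nesting depth, that is
#' privacy-sensitive: standard-defined keys flagged `private` in the
#' registry, user keys whose name starts with `"private_"`, and any names
#' listed in `extra_keys`. Removal is deletion — no placeholder values are
#' written — and the data array is untouched. The mandatory keys are always
#' retained.
#'
#' @param image an `mrs_image` (or bare `mrs_extension`).
#' @param extra_keys optional additional key names to remove wherever they
#'   occur. Naming a mandatory key is refused.
#' @return A list with members `image` (anonymized copy, same class as the
#'   input) and `removed` (character vector of dotted key paths).
#' @examples
#' img <- gen_example("mrsi_proc")
#' res <- mrs_anonymize(img)
#' res$removed   # e.g. "PatientName", "PatientID", ...
#' @export
mrs_anonymize <- function(image, extra_keys = NULL) {
  extra_keys <- as.character(extra_keys %||% character(0))
  if (any(extra_keys %in% MANDATORY_KEYS))
    stop_mrs("refusing to remove a mandatory key", "mrs_mandatory_error")
  ext <- if (inherits(image, "mrs_image")) image$extension else image
  stopifnot(inherits(ext, "mrs_extension"))
  res_std <- prune_private(ext$standard_keys, "", extra_keys)
  res_usr <- prune_private(ext$user_keys, "", extra_keys)
  removed <- c(res_std$removed, res_usr$removed)
  ext$standard_keys <- res_std$value
  ext$user_keys <- res_usr$value
  for (n in names(ext$dim_headers)) {
    res <- prune_private(ext$dim_headers[[n]], paste0("dim_", n, "_header"),
                         extra_keys)
    ext$dim_headers[[n]] <- res$value
    removed <- c(removed, res$removed)
  }
  if (length(ext$processing_applied) > 0L) {
    for (i in seq_along(ext$processing_applied)) {
      res <- prune_private(ext$processing_applied[[i]],
                           sprintf("ProcessingApplied[%d]", i - 1L), extra_keys)
      ext$processing_applied[[i]] <- res$value
      removed <- c(removed, res$removed)
    }
  }
  if (inherits(image, "mrs_image")) image$extension <- ext else image <- ext
  list(image = image, removed = removed)
}
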