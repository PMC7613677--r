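# Tagging the dynamic dimensions of an image.

#' Tag a dynamic dimension
#'
#' Sets the `dim_{n}` tag (and optionally `dim_{n}_info` and
#' `dim_{n}_header`) for dimension `n` of an image. Long-form dynamic
#' header arrays are checked against the dimension's size; compact
#' `{start, increment}` specifications are normalized to long form so that
#' written files are canonical, with any `{Value, Description}` wrapper
#' preserved.
#'
#' @param image an `mrs_image` whose data has a dimension `n`.
#' @param n 5, 6 or 7.
#' @param tag a tag from [dim_tag_vocabulary()] (`DIM_COIL`, `DIM_DYN`,
#'   `DIM_INDIRECT`, `DIM_EDIT`, `DIM_ISIS`, `DIM_PHASE_CYCLE`, `DIM_MEAS`,
#'   or `DIM_USER_{0-2}`).
#' @param info optional free-text description (recommended for
#'   `DIM_USER_*`).
#' @param header optional named list of dynamic header specifications.
#' @return The modified `mrs_image`.
#' @examples
#' img <- gen_example("svs_raw")
#' img <- set_dim_tag(img, 6, "DIM_MEAS")
#' @export
set_dim_tag <- function(image, n, tag, info = NULL, header = NULL) {
  stopifnot(inherits(image, "mrs_image"), n %in% 5:7)
  if (!tag %in% valid_dim_tags())
    stop_mrs(sprintf("unknown dimension tag '%s'", tag), "mrs_tag_error")
  d <- c(image$header$dim[-1], rep(1L, 7L))[1:7]
  if (image$header$dim[1] < n)
    stop_mrs(sprintf("image has rank %d; dimension %d does not exist",
                     image$header$dim[1], n), "mrs_rank_error")
  key <- as.character(n)
  image$extension$dim_tags[[key]] <- tag
  if (!is.null(info)) image$extension$dim_infos[[key]] <- as.character(info)
  if (!is.null(header)) {
    stopifnot(is.list(header), !is.null(names(header)))
    norm <- lapply(header, function(spec) {
      len <- dyn_length(spec)
      if (!is.na(len) && len != d[n])
        stop_mrs(sprintf("dynamic header array has length %d but dimension %d has size %d",
                         len, n, d[n]), "mrs_shape_error")
      long <- expand_dyn(spec, d[n])
      if (is.list(spec) && !is.null(spec$Value))
        list(Value = long, Description = spec$Description)
      else long
    })
    image$extension$dim_headers[[key]] <- norm
  }
  image
}
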