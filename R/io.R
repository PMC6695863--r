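#' Plain-text gridded-field files
#'
#' Fields are stored as a JSON document carrying CF-style coordinate
#' variables (`lon`, `lat`, and when present `layer` and `time`), the array
#' shape, a fill value standing in for dry cells, and the data at full
#' decimal precision, so a write/read cycle restores the array bitwise and
#' dry cells come back as `NA`. Several variables can live in one file.
#'
#' @param fields named list of arrays/matrices (or a single array with
#'   `variable` naming it); `NA` entries are written as the fill value
#' @param grid an `npzd_grid` providing the coordinate variables
#' @param path output file
#' @param variable variable name when `fields` is a bare array
#' @param time optional numeric time coordinate (hours) for fields with a
#'   time dimension
#' @return `path`, invisibly
#' @export
write_field <- function(fields, grid, path, variable = "field", time = NULL) {
  stopifnot(inherits(grid, "npzd_grid"))
  if (!is.list(fields)) fields <- stats::setNames(list(fields), variable)
  fill <- -9.99e33
  vars <- lapply(fields, function(a) {
    a <- as.array(a)
    vals <- as.numeric(a)
    vals[!is.finite(vals)] <- fill
    list(shape = dim(a), values = vals)
  })
  doc <- list(
    conventions = "CF-style coordinates, column-major values",
    coords = list(lon = grid$lon, lat = grid$lat,
                  layer = seq_len(grid$nz) - 1L,
                  layer_mid_m = grid$layer_mid,
                  time_hours = time),
    fill_value = fill,
    variables = vars)
  # I(17) significant digits: doubles survive the decimal round trip bitwise
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @param path file written by [write_field()]
#' @return `read_field`: list with `values` (array, `NA` on dry cells) and
#'   `coords`
#' @export
read_field <- function(path, variable = "field") {
  if (!file.exists(path)) stop("no such field file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$coords$lon) || is.null(doc$coords$lat)) {
    stop("not a gridded-field file: expected CF-style lon/lat coordinates")
  }
  if (!variable %in% names(doc$variables)) {
    stop(sprintf("variable '%s' not found; available: %s", variable,
                 paste(names(doc$variables), collapse = ", ")))
  }
  v <- doc$variables[[variable]]
  a <- array(as.numeric(v$values), dim = v$shape)
  a[a == doc$fill_value] <- NA_real_
  list(values = a, coords = doc$coords)
}
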