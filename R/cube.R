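#' Daily gridded cube
#'
#' The central container of the package: a daily three-dimensional field with
#' dimensions time x latitude x longitude. It carries either a fire-danger
#' index (e.g. the dimensionless Canadian Fire Weather Index, FWI) or an
#' observed quantity such as burned area in hectares. Missing cells are
#' encoded as `NA` in `values`.
#'
#' All functions in the package assume WGS84 coordinates with longitudes in
#' the range \[-180, 180); cubes read from model output with 0--360 longitudes
#' should be passed through [rotate_longitudes()] first.
#'
#' @param values numeric array of dimension `c(n_time, n_lat, n_lon)`.
#' @param dates `Date` vector, one entry per time slice, strictly increasing.
#' @param lats numeric vector of cell-center latitudes (degrees north),
#'   strictly monotonic (either direction).
#' @param lons numeric vector of cell-center longitudes (degrees east),
#'   strictly monotonic, within \[-180, 180\].
#' @param units free-text units tag (e.g. `""` for FWI, `"hectares"`).
#'
#' @return An object of class `fire_cube` with fields `values`, `dates`,
#'   `lats`, `lons`, `units`.
#' @seealso [fire_grid()] for a single time slice, [read_cube()],
#'   [write_cube()].
#' @export
fire_cube <- function(values, dates, lats, lons, units = "") {
  values <- as_cube_array(values)
  dates <- as.Date(dates)
  lats <- as.numeric(lats)
  lons <- as.numeric(lons)
  dm <- dim(values)
  if (length(dates) != dm[1]) {
    stop("length(dates) [", length(dates), "] != time dimension [", dm[1], "]")
  }
  if (length(lats) != dm[2] || length(lons) != dm[3]) {
    stop("coordinate lengths (", length(lats), ", ", length(lons),
         ") do not match spatial dimensions (", dm[2], ", ", dm[3], ")")
  }
  if (anyNA(dates)) stop("dates contain NA")
  if (length(dates) > 1 && any(diff(as.numeric(dates)) <= 0)) {
    stop("dates must be strictly increasing")
  }
  check_monotonic(lats, "lats")
  check_monotonic(lons, "lons")
  # 0-360 grids are accepted so they can be passed to rotate_longitudes();
  # every analysis function assumes the normalized [-180, 180) convention.
  if (any(lons < -180 | lons >= 360)) {
    stop("lons outside [-180, 360); not a recognised longitude convention")
  }
  structure(
    list(values = values, dates = dates, lats = lats, lons = lons,
         units = as.character(units)),
    class = "fire_cube"
  )
}

#' Single-layer gridded field
#'
#' A two-dimensional \[lat, lon\] field, the natural result of collapsing a
#' [fire_cube()] over time (e.g. a percentile map) or of subsetting it to one
#' time slice.
#'
#' @param values numeric matrix `[lat, lon]`.
#' @param lats,lons,units as in [fire_cube()].
#' @return An object of class `fire_grid`.
#' @export
fire_grid <- function(values, lats, lons, units = "") {
  values <- as.matrix(values)
  lats <- as.numeric(lats)
  lons <- as.numeric(lons)
  if (nrow(values) != length(lats) || ncol(values) != length(lons)) {
    stop("matrix dimensions do not match coordinate lengths")
  }
  check_monotonic(lats, "lats")
  check_monotonic(lons, "lons")
  structure(
    list(values = values, lats = lats, lons = lons, units = as.character(units)),
    class = "fire_grid"
  )
}

as_cube_array <- function(values) {
  if (is.null(dim(values))) stop("values must be a 3-D array [time, lat, lon]")
  if (length(dim(values)) != 3) stop("values must have exactly 3 dimensions")
  storage.mode(values) <- "double"
  values
}

check_monotonic <- function(x, name) {
  if (length(x) < 1) stop(name, " is empty")
  if (length(x) > 1) {
    d <- diff(x)
    if (!(all(d > 0) || all(d < 0))) {
      stop(name, " must be strictly monotonic")
    }
  }
  invisible(x)
}

#' @export
print.fire_cube <- function(x, ...) {
  dm <- dim(x$values)
  cat("<fire_cube> ", dm[1], " days x ", dm[2], " lat x ", dm[3], " lon\n",
      sep = "")
  cat("  dates: ", format(x$dates[1]), " .. ", format(x$dates[dm[1]]), "\n",
      sep = "")
  cat("  lats:  ", round(min(x$lats), 3), " .. ", round(max(x$lats), 3),
      "   lons: ", round(min(x$lons), 3), " .. ", round(max(x$lons), 3), "\n",
      sep = "")
  if (nzchar(x$units)) cat("  units: ", x$units, "\n", sep = "")
  invisible(x)
}

#' @export
print.fire_grid <- function(x, ...) {
  cat("<fire_grid> ", nrow(x$values), " lat x ", ncol(x$values), " lon\n",
      sep = "")
  if (nzchar(x$units)) cat("  units: ", x$units, "\n", sep = "")
  invisible(x)
}

n_times <- function(cube) dim(cube$values)[1]

is_fire_cube <- function(x) inherits(x, "fire_cube")
is_fire_grid <- function(x) inherits(x, "fire_grid")

#' Rotate longitudes from 0--360 to -180--180
#'
#' Global weather and fire-danger model output is commonly distributed on a
#' 0--360 longitude grid, while administrative polygons and satellite burned
#' areas use -180--180. This function relabels each longitude `l >= 180` as
#' `l - 360` and reorders the columns so longitudes ascend. It is a pure
#' permutation: no interpolation takes place and every cell value is
#' preserved exactly.
#'
#' @param cube a [fire_cube()] (or [fire_grid()]) with longitudes in
#'   \[0, 360). A cube already in -180--180 convention is returned unchanged
#'   with a warning.
#' @return The rotated object, same class as the input.
#' @export
rotate_longitudes <- function(cube) {
  lons <- cube$lons
  if (all(lons >= -180 & lons < 180)) {
    warning("longitudes already within [-180, 180); returning input unchanged")
    return(cube)
  }
  if (any(lons < 0) || any(lons >= 360)) {
    stop("longitudes must lie in [0, 360) before rotation")
  }
  new_lons <- ifelse(lons >= 180, lons - 360, lons)
  ord <- order(new_lons)
  if (is_fire_grid(cube)) {
    fire_grid(cube$values[, ord, drop = FALSE], cube$lats, new_lons[ord],
              cube$units)
  } else {
    fire_cube(cube$values[, , ord, drop = FALSE], cube$dates, cube$lats,
              new_lons[ord], cube$units)
  }
}
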