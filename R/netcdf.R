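#' Read a daily gridded field from NetCDF
#'
#' Reads a variable with time/latitude/longitude dimensions from a CF-style
#' NetCDF file into a [fire_cube()]. The time coordinate is parsed from its
#' `units` attribute (`"<unit> since <origin>"`, with unit one of seconds,
#' hours or days); if the file carries no usable time coordinate, dates must
#' be supplied explicitly via `dates`. Cells equal to the variable's
#' `_FillValue`/`missing_value` become `NA`. Longitudes on a 0--360 grid are
#' normalized to -180--180 on ingest (see [rotate_longitudes()]).
#'
#' @param path path to a NetCDF file.
#' @param varname name of the variable to extract. If `NULL` and the file
#'   holds a single non-coordinate variable, that variable is used.
#' @param dates optional `Date` vector overriding the file's time axis
#'   (required when the time axis is absent or unparseable).
#' @return A [fire_cube()].
#' @export
read_cube <- function(path, varname = NULL, dates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  available <- names(nc$var)
  if (is.null(varname)) {
    if (length(available) != 1) {
      stop("varname must be given; file holds variables: ",
           paste(available, collapse = ", "))
    }
    varname <- available
  }
  if (!varname %in% available) {
    stop("variable '", varname, "' not found; available: ",
         paste(available, collapse = ", "))
  }
  v <- nc$var[[varname]]
  dim_names <- vapply(v$dim, function(d) d$name, character(1))
  i_lon <- match_dim(dim_names, c("lon", "longitude", "x"))
  i_lat <- match_dim(dim_names, c("lat", "latitude", "y"))
  i_time <- match_dim(dim_names, c("time", "t"))
  if (anyNA(c(i_lon, i_lat, i_time))) {
    stop("variable '", varname, "' lacks time/lat/lon dimensions (found: ",
         paste(dim_names, collapse = ", "), ")")
  }
  vals <- ncdf4::ncvar_get(nc, varname, collapse_degen = FALSE)
  # reorder whatever the on-disk layout is into [time, lat, lon]
  vals <- aperm(vals, c(i_time, i_lat, i_lon))
  lats <- v$dim[[i_lat]]$vals
  lons <- v$dim[[i_lon]]$vals
  if (is.null(dates)) {
    tdim <- v$dim[[i_time]]
    dates <- parse_time_axis(tdim$vals, tdim$units)
  } else {
    dates <- as.Date(dates)
    if (length(dates) != dim(vals)[1]) {
      stop("supplied dates length does not match the time dimension")
    }
  }
  units <- ncdf4::ncatt_get(nc, varname, "units")
  units <- if (isTRUE(units$hasatt)) units$value else ""
  cube <- fire_cube(vals, dates, lats, lons, units)
  if (any(cube$lons >= 180)) cube <- rotate_longitudes(cube)
  cube
}

match_dim <- function(dim_names, candidates) {
  hit <- match(candidates, tolower(dim_names))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) NA_integer_ else hit[1]
}

parse_time_axis <- function(vals, units) {
  if (is.null(units) || !nzchar(units)) {
    stop("time axis has no units attribute; pass dates= explicitly")
  }
  m <- regmatches(units, regexec(
    "^(second|sec|hour|day)s?\\s+since\\s+(\\d{4}-\\d{2}-\\d{2})", units,
    ignore.case = TRUE))[[1]]
  if (length(m) == 0) {
    stop("unparseable time axis units '", units, "'; pass dates= explicitly")
  }
  per_day <- switch(tolower(m[2]), second = 86400, sec = 86400, hour = 24,
                    day = 1)
  origin <- as.Date(m[3])
  origin + floor(as.numeric(vals) / per_day)
}

#' Write a cube to NetCDF
#'
#' Writes a [fire_cube()] as a CF-style NetCDF file with dimensions
#' (time, latitude, longitude), coordinate variables, a
#' `"days since 1970-01-01"` time axis and a fill value for missing cells.
#'
#' @param cube a [fire_cube()].
#' @param path output file path.
#' @param varname variable name to store the field under.
#' @return `path`, invisibly usable in pipelines.
#' @export
write_cube <- function(cube, path, varname = "fwi") {
  stopifnot(is_fire_cube(cube))
  fill <- -9999
  dim_lon <- ncdf4::ncdim_def("longitude", "degrees_east", cube$lons)
  dim_lat <- ncdf4::ncdim_def("latitude", "degrees_north", cube$lats)
  dim_time <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                               as.numeric(cube$dates), unlim = TRUE)
  var <- ncdf4::ncvar_def(varname, cube$units, list(dim_lon, dim_lat, dim_time),
                          missval = fill, prec = "double")
  nc <- ncdf4::nc_create(path, list(var))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, aperm(cube$values, c(3, 2, 1)))
  path
}

#' Decompress every gzip archive in a directory
#'
#' Replaces each `*.gz` file in `input_dir` by its decompressed counterpart
#' (e.g. `file.nc.gz` becomes `file.nc`) and removes the archive once its
#' content has been extracted. Non-archive files are left untouched. A
#' corrupt archive does not stop the others from being processed; it is
#' reported by name in the final error.
#'
#' @param input_dir directory to scan (non-recursively) for `*.gz` files.
#' @return Character vector of decompressed file paths (invisibly the empty
#'   vector when the directory holds no archives).
#' @export
decompress_gz_dir <- function(input_dir) {
  if (!dir.exists(input_dir)) stop("directory not found: ", input_dir)
  archives <- list.files(input_dir, pattern = "\\.gz$", full.names = TRUE)
  done <- character(0)
  failed <- character(0)
  for (f in archives) {
    out <- sub("\\.gz$", "", f)
    # gzip corruption may surface as a warning or an error; either voids it
    ok <- tryCatch({
      gunzip_file(f, out)
      TRUE
    }, warning = function(w) {
      unlink(out)
      FALSE
    }, error = function(e) {
      unlink(out)
      FALSE
    })
    if (ok) {
      unlink(f)
      done <- c(done, out)
    } else {
      failed <- c(failed, basename(f))
    }
  }
  if (length(failed) > 0) {
    stop("failed to decompress: ", paste(failed, collapse = ", "),
         " (", length(done), " other archive(s) processed)")
  }
  done
}

# streamed copy so working storage stays bounded regardless of archive size
gunzip_file <- function(src, dest, chunk = 2^20) {
  con_in <- gzfile(src, "rb")
  on.exit(close(con_in), add = TRUE)
  con_out <- file(dest, "wb")
  on.exit(close(con_out), add = TRUE)
  repeat {
    buf <- readBin(con_in, "raw", n = chunk)
    if (length(buf) == 0) break
    writeBin(buf, con_out)
  }
  invisible(dest)
}

#' Import a tar archive of gzipped single-day NetCDF files
#'
#' Fire-danger reanalysis is commonly distributed as a tar archive holding
#' one gzip-compressed NetCDF file per day. This function unpacks the
#' archive into a temporary directory, decompresses the members, reads each
#' one and merges the layers into a single cube ordered by date (member
#' naming order is irrelevant).
#'
#' @param archive path to the tar file.
#' @param varname variable to extract from each member; `NULL` picks the
#'   single variable each file holds.
#' @return A [fire_cube()] with one slice per member day.
#' @export
import_from_tar <- function(archive, varname = NULL) {
  if (!file.exists(archive)) stop("archive not found: ", archive)
  exdir <- tempfile("untar")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  utils::untar(archive, exdir = exdir)
  members <- list.files(exdir, recursive = TRUE, full.names = TRUE)
  gz <- members[grepl("\\.gz$", members)]
  for (f in gz) {
    gunzip_file(f, sub("\\.gz$", "", f))
    unlink(f)
  }
  ncs <- list.files(exdir, pattern = "\\.nc$", recursive = TRUE,
                    full.names = TRUE)
  if (length(ncs) == 0) stop("archive holds no NetCDF members: ", archive)
  cubes <- lapply(ncs, read_cube, varname = varname)
  cubes <- cubes[order(vapply(cubes, function(x) as.numeric(x$dates[1]),
                              numeric(1)))]
  cube_bind_time(cubes)
}

# concatenate cubes along time; grids must agree exactly
cube_bind_time <- function(cubes) {
  stopifnot(length(cubes) >= 1)
  ref <- cubes[[1]]
  for (cb in cubes[-1]) {
    if (!isTRUE(all.equal(cb$lats, ref$lats)) ||
        !isTRUE(all.equal(cb$lons, ref$lons))) {
      stop("grid mismatch between stacked layers (",
           paste(dim(cb$values)[2:3], collapse = "x"), " vs ",
           paste(dim(ref$values)[2:3], collapse = "x"), ")")
    }
  }
  nt <- vapply(cubes, n_times, integer(1))
  vals <- array(NA_real_, dim = c(sum(nt), length(ref$lats), length(ref$lons)))
  at <- 0L
  for (cb in cubes) {
    vals[at + seq_len(n_times(cb)), , ] <- cb$values
    at <- at + n_times(cb)
  }
  dates <- as.Date(unlist(lapply(cubes, function(x) x$dates)),
                   origin = "1970-01-01")
  fire_cube(vals, dates, ref$lats, ref$lons, ref$units)
}

#' Merge daily NetCDF files over the time dimension
#'
#' Concatenates many single-day (or multi-day) NetCDF files found in a
#' directory into one file along the time axis, extracting only the variable
#' of interest. Files are stacked in lexicographic filename order, which is
#' assumed to coincide with time order under a consistent naming convention;
#' set `sort_by_date = TRUE` to sort by each file's first date instead (at
#' the cost of reading all headers before deciding the order).
#'
#' @param input_dir directory holding the input files.
#' @param varname variable to extract; `NULL` for single-variable files.
#' @param pattern optional regular expression selecting a subset of the
#'   `.nc` files by filename.
#' @param recursive if `TRUE`, subdirectories are searched too.
#' @param output_file path of the merged NetCDF file to create.
#' @param sort_by_date verify/enforce time order by sorting on each file's
#'   first date rather than trusting filename order.
#' @return `output_file`.
#' @export
stack_time_files <- function(input_dir, varname = NULL, pattern = NULL,
                             recursive = FALSE,
                             output_file = file.path(input_dir, "output.nc"),
                             sort_by_date = FALSE) {
  if (!dir.exists(input_dir)) stop("directory not found: ", input_dir)
  files <- list.files(input_dir, pattern = "\\.nc$", recursive = recursive,
                      full.names = TRUE)
  if (!is.null(pattern)) files <- files[grepl(pattern, basename(files))]
  if (length(files) > 0) {
    files <- files[normalizePath(files) !=
                     normalizePath(output_file, mustWork = FALSE)]
  }
  files <- files[order(basename(files))]
  if (length(files) == 0) stop("no NetCDF files matched in ", input_dir)
  cubes <- lapply(files, read_cube, varname = varname)
  if (sort_by_date) {
    cubes <- cubes[order(vapply(cubes, function(x) as.numeric(x$dates[1]),
                                numeric(1)))]
  }
  merged <- cube_bind_time(cubes)
  out_var <- if (is.null(varname)) "fwi" else varname
  write_cube(merged, output_file, out_var)
  output_file
}
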