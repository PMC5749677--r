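#' Region of interest polygon
#'
#' A WGS84 polygon or multipolygon delimiting the area over which danger
#' levels are calibrated or verified (a country, a region, a basin). Rings
#' are closed coordinate matrices; containment uses the even-odd rule, so
#' interior rings act as holes and multipart regions (e.g. a mainland plus
#' islands) are handled as the union of their parts.
#'
#' @param rings a single two-column (lon, lat) matrix or a list of them;
#'   each ring must be closed (first vertex equal to last) and have at least
#'   three distinct vertices.
#' @param id label for the region (e.g. `"EURO"`, `"Italy"`, `"Liguria"`).
#' @return An object of class `region_polygon`.
#' @export
region_polygon <- function(rings, id = "region") {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2) stop("each ring must be a two-column (lon, lat) matrix")
    if (!isTRUE(all.equal(r[1, ], r[nrow(r), ], check.attributes = FALSE))) {
      stop("ring is not closed (first vertex != last vertex)")
    }
    if (nrow(unique(r)) < 3) stop("ring has fewer than 3 distinct vertices")
    if (any(r[, 1] < -180 | r[, 1] > 180)) {
      stop("ring longitudes outside [-180, 180]")
    }
    r
  })
  structure(list(rings = rings, id = as.character(id)),
            class = "region_polygon")
}

#' Rectangle region helper
#'
#' @param xmin,xmax,ymin,ymax bounding coordinates in degrees.
#' @param id region label.
#' @return A [region_polygon()] with a single rectangular ring.
#' @export
rect_region <- function(xmin, xmax, ymin, ymax, id = "rect") {
  ring <- cbind(c(xmin, xmax, xmax, xmin, xmin),
                c(ymin, ymin, ymax, ymax, ymin))
  region_polygon(ring, id)
}

#' @export
print.region_polygon <- function(x, ...) {
  nv <- sum(vapply(x$rings, nrow, integer(1)))
  cat("<region_polygon> '", x$id, "': ", length(x$rings), " ring(s), ",
      nv, " vertices\n", sep = "")
  invisible(x)
}

#' Read a region polygon from GeoJSON
#'
#' Supports Polygon and MultiPolygon geometries, bare or wrapped in a
#' Feature/FeatureCollection; all parts are collected into one
#' [region_polygon()] (multipart regions are treated as a union).
#'
#' @param path path to a GeoJSON file (WGS84 coordinates).
#' @param id region label; defaults to a `name`/`id` property when present,
#'   else the file name.
#' @return A [region_polygon()].
#' @export
read_region_geojson <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::read_json(path)
  geoms <- list()
  label <- NULL
  collect <- function(obj) {
    type <- obj$type
    if (is.null(type)) stop("invalid GeoJSON: object without type")
    if (type == "FeatureCollection") {
      for (f in obj$features) collect(f)
    } else if (type == "Feature") {
      nm <- obj$properties$name
      if (is.null(nm)) nm <- obj$properties$id
      if (!is.null(nm) && is.null(label)) label <<- nm
      collect(obj$geometry)
    } else if (type %in% c("Polygon", "MultiPolygon")) {
      geoms[[length(geoms) + 1]] <<- obj
    } else {
      stop("unsupported GeoJSON geometry type: ", type)
    }
  }
  collect(gj)
  if (length(geoms) == 0) stop("no Polygon/MultiPolygon geometry in ", path)
  rings <- list()
  add_ring <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(pt) {
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
    }))
    rings[[length(rings) + 1]] <<- m
  }
  for (g in geoms) {
    if (g$type == "Polygon") {
      for (ring in g$coordinates) add_ring(ring)
    } else {
      for (poly in g$coordinates) for (ring in poly) add_ring(ring)
    }
  }
  if (is.null(id)) {
    id <- if (!is.null(label)) label else
      tools::file_path_sans_ext(basename(path))
  }
  region_polygon(rings, id)
}

#' Write a region polygon to GeoJSON
#'
#' @param region a [region_polygon()].
#' @param path output file path.
#' @return `path`.
#' @export
write_region_geojson <- function(region, path) {
  stopifnot(inherits(region, "region_polygon"))
  polys <- lapply(region$rings, function(r) list(apply(r, 1, as.list)))
  obj <- list(
    type = "Feature",
    properties = list(name = region$id),
    geometry = list(type = "MultiPolygon", coordinates = polys)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  path
}

# even-odd containment for point vectors; edge and vertex hits count inside
points_in_region <- function(px, py, region) {
  inside <- rep(FALSE, length(px))
  crossings <- rep(0L, length(px))
  for (ring in region$rings) {
    pip <- sp::point.in.polygon(px, py, ring[, 1], ring[, 2])
    inside <- inside | pip >= 2          # on an edge or a vertex
    crossings <- crossings + as.integer(pip == 1)
  }
  inside | (crossings %% 2L == 1L)
}

region_bbox <- function(region) {
  all_pts <- do.call(rbind, region$rings)
  c(xmin = min(all_pts[, 1]), xmax = max(all_pts[, 1]),
    ymin = min(all_pts[, 2]), ymax = max(all_pts[, 2]))
}

# half cell widths; a single-coordinate axis gets an arbitrary small width
half_step <- function(coords) {
  if (length(coords) < 2) return(rep(0.5, length(coords)))
  d <- abs(diff(coords))
  rep(stats::median(d) / 2, length(coords))
}

cell_inside_matrix <- function(lats, lons, region, inclusion = "center") {
  pts <- expand.grid(lat = lats, lon = lons)   # lat varies fastest, as in the
  inside <- points_in_region(pts$lon, pts$lat, region)  # [lat, lon] layout
  if (inclusion == "any") {
    hy <- half_step(lats)[1]
    hx <- half_step(lons)[1]
    for (sx in c(-hx, hx)) for (sy in c(-hy, hy)) {
      inside <- inside | points_in_region(pts$lon + sx, pts$lat + sy, region)
    }
  }
  matrix(inside, nrow = length(lats), ncol = length(lons))
}

#' Mask, crop and subset a gridded field
#'
#' The workhorse spatial selector: restrict a cube (or single-layer grid) to
#' a region of interest and, optionally, to a subset of time slices. Masking
#' sets cells outside the region to missing; cropping cuts the spatial
#' extent down to the region's bounding box, snapped outward to whole cells
#' so no partial cells are created. Surviving cell values are never altered.
#'
#' @param r a [fire_cube()] or [fire_grid()].
#' @param p a [region_polygon()].
#' @param mask if `TRUE` (default), cells outside `p` become `NA`.
#' @param crop if `TRUE` (default), the extent is reduced to `p`'s bounding
#'   box.
#' @param idx optional vector of time indices to retain (cube input only).
#' @param inclusion cell-inclusion rule for masking: `"center"` (default; a
#'   cell belongs to the region iff its center does, points on an edge
#'   counting as inside) or `"any"` (a cell is kept if its center or any
#'   corner falls inside — a cheap approximation of fractional overlap).
#' @return A [fire_cube()], or a [fire_grid()] when a single time slice
#'   remains (or when the input was one).
#' @export
mask_crop_subset <- function(r, p, mask = TRUE, crop = TRUE, idx = NULL,
                             inclusion = c("center", "any")) {
  inclusion <- match.arg(inclusion)
  stopifnot(inherits(p, "region_polygon"))
  grid_in <- is_fire_grid(r)
  if (grid_in) {
    if (!is.null(idx)) stop("idx cannot be used with a single-layer grid")
    cube <- fire_cube(array(r$values, c(1, nrow(r$values), ncol(r$values))),
                      as.Date("1970-01-01"), r$lats, r$lons, r$units)
  } else {
    stopifnot(is_fire_cube(r))
    cube <- r
  }
  if (!is.null(idx)) {
    idx <- as.integer(idx)
    if (any(idx < 1 | idx > n_times(cube))) {
      stop("idx out of range 1..", n_times(cube))
    }
    cube <- fire_cube(cube$values[idx, , , drop = FALSE], cube$dates[idx],
                      cube$lats, cube$lons, cube$units)
  }
  lats <- cube$lats
  lons <- cube$lons
  keep_lat <- rep(TRUE, length(lats))
  keep_lon <- rep(TRUE, length(lons))
  if (crop) {
    bb <- region_bbox(p)
    hy <- half_step(lats)
    hx <- half_step(lons)
    keep_lat <- (lats + hy) > bb["ymin"] & (lats - hy) < bb["ymax"]
    keep_lon <- (lons + hx) > bb["xmin"] & (lons - hx) < bb["xmax"]
    if (!any(keep_lat) || !any(keep_lon)) stop("empty overlap")
  }
  vals <- cube$values[, keep_lat, keep_lon, drop = FALSE]
  lats <- lats[keep_lat]
  lons <- lons[keep_lon]
  if (mask) {
    inside <- cell_inside_matrix(lats, lons, p, inclusion)
    if (!any(inside)) stop("empty overlap")
    nt <- dim(vals)[1]
    flat <- matrix(vals, nrow = nt)
    flat[, !as.vector(inside)] <- NA_real_
    vals <- array(flat, dim(vals))
  }
  out <- fire_cube(vals, cube$dates, lats, lons, cube$units)
  if (grid_in || n_times(out) == 1) {
    fire_grid(out$values[1, , ], out$lats, out$lons, out$units)
  } else {
    out
  }
}

#' Nearest-neighbour regridding
#'
#' Assigns to each target cell the value of the source cell whose center is
#' nearest (axis-wise, which on rectilinear grids is the overall nearest
#' center). Used to bring higher-resolution burned-area observations onto
#' the coarser fire-danger grid; being a pure value lookup it keeps binary
#' fields binary. Axis-wise distance ties resolve to the first (lower-index)
#' source cell.
#'
#' @param src a [fire_cube()] or [fire_grid()].
#' @param target_lats,target_lons coordinate vectors of the target grid.
#' @return Object of the same class as `src` on the target grid.
#' @export
resample_nearest <- function(src, target_lats, target_lons) {
  target_lats <- as.numeric(target_lats)
  target_lons <- as.numeric(target_lons)
  if (length(target_lats) == 0 || length(target_lons) == 0) {
    stop("empty target axes")
  }
  check_monotonic(target_lats, "target_lats")
  check_monotonic(target_lons, "target_lons")
  i_lat <- vapply(target_lats, function(y) which.min(abs(src$lats - y)),
                  integer(1))
  i_lon <- vapply(target_lons, function(x) which.min(abs(src$lons - x)),
                  integer(1))
  if (is_fire_grid(src)) {
    fire_grid(src$values[i_lat, i_lon, drop = FALSE], target_lats,
              target_lons, src$units)
  } else {
    fire_cube(src$values[, i_lat, i_lon, drop = FALSE], src$dates,
              target_lats, target_lons, src$units)
  }
}

#' Fuel-model code grid
#'
#' An integer land-cover/fuel classification raster. Codes 21--27 mark
#' non-burnable surfaces (water, barren, marsh, snow and ice, urban,
#' agriculture, no-data) and are excluded from fire-danger analysis.
#'
#' @param codes integer matrix `[lat, lon]` of fuel-model codes.
#' @param lats,lons cell-center coordinates.
#' @param nonburnable integer codes treated as non-burnable (default 21:27).
#' @return An object of class `fuel_grid`.
#' @export
fuel_grid <- function(codes, lats, lons, nonburnable = 21:27) {
  codes <- as.matrix(codes)
  if (any(codes < 0, na.rm = TRUE)) stop("fuel codes must be non-negative")
  if (nrow(codes) != length(lats) || ncol(codes) != length(lons)) {
    stop("code matrix does not match coordinate lengths")
  }
  structure(list(codes = codes, lats = as.numeric(lats),
                 lons = as.numeric(lons),
                 nonburnable = as.integer(nonburnable)),
            class = "fuel_grid")
}

#' Mask out non-burnable cells using a fuel-model grid
#'
#' Sets to missing every cell whose fuel-model code is non-burnable; all
#' other values pass through untouched. The fuel grid must be co-registered
#' with the field (resample one of them first if not).
#'
#' @param r a [fire_cube()] or [fire_grid()].
#' @param fuel a [fuel_grid()] on the same coordinates as `r`.
#' @return Same class as `r` with non-burnable cells set to `NA`.
#' @export
mask_with_fuelmodel <- function(r, fuel) {
  stopifnot(inherits(fuel, "fuel_grid"))
  if (!isTRUE(all.equal(r$lats, fuel$lats)) ||
      !isTRUE(all.equal(r$lons, fuel$lons))) {
    stop("fuel grid not aligned with the field; resample_nearest() first")
  }
  bad <- fuel$codes %in% fuel$nonburnable
  bad <- matrix(bad, nrow = nrow(fuel$codes))
  if (is_fire_grid(r)) {
    v <- r$values
    v[bad] <- NA_real_
    fire_grid(v, r$lats, r$lons, r$units)
  } else {
    nt <- n_times(r)
    flat <- matrix(r$values, nrow = nt)
    flat[, as.vector(bad)] <- NA_real_
    fire_cube(array(flat, dim(r$values)), r$dates, r$lats, r$lons, r$units)
  }
}
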