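#' Specification for synthetic fire-danger data
#'
#' Describes a reproducible synthetic study domain: a multi-year daily FWI
#' cube with a seasonal cycle and spatially varying right-skewed marginals,
#' and a companion burned-area cube whose large-fire probability rises with
#' FWI through a logistic link. Everything downstream of the generators is a
#' pure function of this spec.
#'
#' Defaults mimic the coarse European reanalysis setting the package
#' targets: a 10 x 10 cell domain at 1 degree spacing over western Europe,
#' five years of daily data, gamma marginals whose scale grows toward the
#' south (warmer cells see stochastically larger FWI), a seasonal
#' modulation peaking mid fire season, and log-normal fire sizes with
#' median 10 ha and about 20 percent of events exceeding the 50 ha
#' large-fire cutoff.
#'
#' @param n_lat,n_lon grid dimensions.
#' @param years integer vector of calendar years to simulate.
#' @param zone hemisphere convention (`"north"` or `"south"`); fixes the
#'   seasonal peak of the FWI cycle.
#' @param shape gamma shape parameter of the FWI marginal (shared by all
#'   cells; < 2 keeps the distribution right-skewed).
#' @param scale_range range of the gamma scale parameter across the grid;
#'   cells interpolate linearly from the poleward to the equatorward edge.
#' @param seasonal_amplitude relative amplitude of the sinusoidal seasonal
#'   modulation of the scale (0 disables seasonality, making the marginal
#'   analytically tractable).
#' @param link_intercept,link_slope logistic-regression coefficients of the
#'   daily fire-occurrence model: P(fire) = plogis(a + b FWI).
#' @param area_meanlog,area_sdlog log-normal parameters of the burned area
#'   (hectares) of an occurring fire.
#' @param obs_factor integer refinement factor of the observation grid
#'   relative to the FWI grid (default 3, exercising the resampling path).
#' @param seed integer seed making every generator deterministic.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_lat = 10, n_lon = 10, years = 2001:2005,
                     zone = c("north", "south"), shape = 1.2,
                     scale_range = c(4, 12), seasonal_amplitude = 0.6,
                     link_intercept = -4, link_slope = 0.12,
                     area_meanlog = log(10), area_sdlog = 1.91,
                     obs_factor = 3, seed = 42) {
  stopifnot(n_lat >= 1, n_lon >= 1, length(years) >= 1, obs_factor >= 1,
            shape > 0, all(scale_range > 0), seasonal_amplitude >= 0,
            seasonal_amplitude < 1, is.finite(link_slope))
  structure(list(n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
                 years = as.integer(years), zone = match.arg(zone),
                 shape = shape, scale_range = as.numeric(scale_range),
                 seasonal_amplitude = seasonal_amplitude,
                 link_intercept = link_intercept, link_slope = link_slope,
                 area_meanlog = area_meanlog, area_sdlog = area_sdlog,
                 obs_factor = as.integer(obs_factor),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

sim_dates <- function(spec) {
  seq.Date(as.Date(sprintf("%d-01-01", min(spec$years))),
           as.Date(sprintf("%d-12-31", max(spec$years))), by = "day")
}

# lats descending (north to south), 1-degree spacing over a Europe-like box
sim_lats <- function(spec) seq(59.5, by = -1, length.out = spec$n_lat)
sim_lons <- function(spec) seq(-9.5, by = 1, length.out = spec$n_lon)

# per-cell gamma scale: grows toward the equatorward edge of the domain
sim_scales <- function(spec) {
  row_scale <- seq(spec$scale_range[1], spec$scale_range[2],
                   length.out = spec$n_lat)
  matrix(row_scale, nrow = spec$n_lat, ncol = spec$n_lon)
}

# multiplicative seasonal factor, peaking mid fire season
seasonal_factor <- function(dates, amplitude, zone) {
  doy <- as.integer(format(dates, "%j"))
  peak <- if (zone == "north") 198 else 15   # ~17 Jul vs ~15 Jan
  1 + amplitude * cos(2 * pi * (doy - peak) / 365.25)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic daily FWI cube
#'
#' Draws each cell-day from a gamma distribution with the cell's scale
#' parameter modulated by the seasonal factor; with
#' `seasonal_amplitude = 0` every cell's days are i.i.d. gamma with known
#' closed-form quantiles, which is what the calibration recovery checks
#' lean on.
#'
#' @param spec a [sim_spec()].
#' @return A dimensionless [fire_cube()]; bit-identical across calls with
#'   the same spec.
#' @export
make_fwi_cube <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  dates <- sim_dates(spec)
  nt <- length(dates)
  scales <- sim_scales(spec)
  sf <- seasonal_factor(dates, spec$seasonal_amplitude, spec$zone)
  vals <- with_seed(spec$seed, {
    draws <- stats::rgamma(nt * spec$n_lat * spec$n_lon, shape = spec$shape,
                           scale = 1)
    a <- array(draws, dim = c(nt, spec$n_lat, spec$n_lon))
    scale_slice <- array(rep(scales, each = nt),
                         dim = c(nt, spec$n_lat, spec$n_lon))
    a * scale_slice * array(sf, dim = c(nt, spec$n_lat, spec$n_lon))
  })
  fire_cube(vals, dates, sim_lats(spec), sim_lons(spec), units = "")
}

#' Generate a synthetic burned-area cube linked to FWI
#'
#' For every date and cell a fire occurs with probability
#' `plogis(a + b * FWI)` of the parent FWI cell; an occurring fire burns a
#' log-normal area in hectares, otherwise the cell records 0. When
#' `obs_factor > 1` the observations are emitted on a grid finer by that
#' integer factor per axis (each fine cell draws independently, with the
#' occurrence probability of its parent coarse cell), which forces the
#' nearest-neighbour resampling path during verification.
#'
#' @param fwi a [fire_cube()], typically from [make_fwi_cube()].
#' @param spec the [sim_spec()] holding the link and size parameters.
#' @return A [fire_cube()] in hectares on the (possibly refined)
#'   observation grid.
#' @export
make_burned_area_cube <- function(fwi, spec) {
  stopifnot(is_fire_cube(fwi), inherits(spec, "sim_spec"))
  f <- spec$obs_factor
  nt <- n_times(fwi)
  n_lat <- length(fwi$lats) * f
  n_lon <- length(fwi$lons) * f
  parent_lat <- rep(seq_along(fwi$lats), each = f)
  parent_lon <- rep(seq_along(fwi$lons), each = f)
  p_occ <- stats::plogis(spec$link_intercept + spec$link_slope * fwi$values)
  p_fine <- p_occ[, parent_lat, parent_lon, drop = FALSE]
  vals <- with_seed(spec$seed + 1L, {
    occ <- array(stats::rbinom(length(p_fine), 1, as.vector(p_fine)),
                 dim = dim(p_fine))
    sizes <- array(stats::rlnorm(length(p_fine), spec$area_meanlog,
                                 spec$area_sdlog), dim = dim(p_fine))
    occ * sizes
  })
  vals[is.na(p_fine)] <- NA_real_
  # refine each coarse cell into f x f children sharing its center spread
  step_lat <- if (length(fwi$lats) > 1) diff(fwi$lats)[1] else -1
  step_lon <- if (length(fwi$lons) > 1) diff(fwi$lons)[1] else 1
  off <- (seq_len(f) - (f + 1) / 2) / f
  fine_lats <- as.vector(vapply(fwi$lats, function(y) y + off * step_lat,
                                numeric(f)))
  fine_lons <- as.vector(vapply(fwi$lons, function(x) x + off * step_lon,
                                numeric(f)))
  fire_cube(vals, fwi$dates, fine_lats, fine_lons, units = "hectares")
}

#' Generate a synthetic fuel-model grid
#'
#' Random integer fuel codes with approximately the requested fraction of
#' non-burnable cells (codes 21--27), the remainder drawn from the burnable
#' codes 1--20.
#'
#' @param n_lat,n_lon grid dimensions.
#' @param nonburnable_fraction fraction of cells given a non-burnable code.
#' @param seed integer seed.
#' @param lats,lons optional coordinates (defaults match [make_fwi_cube()]
#'   for a same-sized domain).
#' @return A [fuel_grid()].
#' @export
make_fuelmodel_grid <- function(n_lat, n_lon, nonburnable_fraction = 0.3,
                                seed = 42, lats = NULL, lons = NULL) {
  stopifnot(nonburnable_fraction >= 0, nonburnable_fraction <= 1)
  if (is.null(lats)) lats <- seq(59.5, by = -1, length.out = n_lat)
  if (is.null(lons)) lons <- seq(-9.5, by = 1, length.out = n_lon)
  codes <- with_seed(seed, {
    nb <- stats::runif(n_lat * n_lon) < nonburnable_fraction
    out <- integer(n_lat * n_lon)
    out[nb] <- sample(21:27, sum(nb), replace = TRUE)
    out[!nb] <- sample(1:20, sum(!nb), replace = TRUE)
    matrix(out, nrow = n_lat)
  })
  fuel_grid(codes, lats, lons)
}

#' Rectangle region covering part of a synthetic domain
#'
#' Convenience wrapper building a [region_polygon()] around a block of cells
#' of a cube's grid, snapped to cell edges.
#'
#' @param cube a [fire_cube()] or [fire_grid()].
#' @param lat_idx,lon_idx index ranges of the cells to cover.
#' @param id region label.
#' @return A [region_polygon()].
#' @export
cells_region <- function(cube, lat_idx, lon_idx, id = "block") {
  hy <- half_step(cube$lats)[1]
  hx <- half_step(cube$lons)[1]
  lat_sel <- cube$lats[lat_idx]
  lon_sel <- cube$lons[lon_idx]
  rect_region(min(lon_sel) - hx, max(lon_sel) + hx,
              min(lat_sel) - hy, max(lat_sel) + hy, id)
}
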