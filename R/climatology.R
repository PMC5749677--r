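#' Per-cell percentile maps of a daily gridded index
#'
#' Collapses the time dimension of a cube into one map per requested
#' percentile: each cell of the output holds the percentile of that cell's
#' daily time series, missing days excluded. This is the standard way to
#' summarise the local distribution of fire-danger values over a multi-year
#' record.
#'
#' Percentiles use linear interpolation of order statistics with the k-th of
#' n sorted values at cumulative fraction (k-1)/(n-1) (`stats::quantile`
#' type 7); other interpolation rules can be selected via `type`.
#'
#' @param r a [fire_cube()].
#' @param probs percentages in \[0, 100\].
#' @param min_valid minimum number of valid days a cell needs before its
#'   percentile is reported; cells below it become `NA`.
#' @param type quantile interpolation type passed to [stats::quantile()].
#' @return A named list of [fire_grid()] maps, one per element of `probs`
#'   (names like `"p50"`).
#' @export
percentile_raster <- function(r, probs, min_valid = 1, type = 7) {
  stopifnot(is_fire_cube(r))
  probs <- as.numeric(probs)
  if (any(probs < 0 | probs > 100)) stop("probs must lie in [0, 100]")
  nt <- n_times(r)
  flat <- matrix(r$values, nrow = nt)
  nv <- colSums(!is.na(flat))
  qs <- apply(flat, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(rep(NA_real_, length(probs)))
    stats::quantile(x, probs / 100, names = FALSE, type = type)
  })
  qs <- matrix(qs, nrow = length(probs))
  qs[, nv < min_valid] <- NA_real_
  out <- lapply(seq_along(probs), function(i) {
    fire_grid(matrix(qs[i, ], nrow = length(r$lats)), r$lats, r$lons, r$units)
  })
  names(out) <- paste0("p", format(probs, trim = TRUE))
  out
}

month_day <- function(x) {
  if (inherits(x, "Date") || is.character(x) && grepl("^\\d{4}-", x[1])) {
    x <- as.Date(x)
    return(as.integer(format(x, "%m")) * 100L + as.integer(format(x, "%d")))
  }
  # "MM-DD" form
  parts <- strsplit(as.character(x), "-")[[1]]
  if (length(parts) != 2) stop("fss/fse must be a Date or an 'MM-DD' string")
  as.integer(parts[1]) * 100L + as.integer(parts[2])
}

season_bounds <- function(zone = c("north", "south"), fss = NULL, fse = NULL) {
  zone <- match.arg(zone)
  if (xor(is.null(fss), is.null(fse))) {
    stop("fss and fse must be given together")
  }
  if (is.null(fss)) {
    if (zone == "north") list(start = 401L, end = 1031L, wrap = FALSE)
    else list(start = 1001L, end = 430L, wrap = TRUE)
  } else {
    s <- month_day(fss)
    e <- month_day(fse)
    list(start = s, end = e, wrap = s > e)
  }
}

#' Fire-season membership of a date sequence
#'
#' The fire season is the recurring dry-season window within which
#' calibration statistics are computed. By convention it runs 1 April -- 31
#' October in the northern hemisphere and 1 October -- 30 April in the
#' southern hemisphere (the southern window wraps the turn of the year).
#' Custom bounds override the convention and are interpreted as recurring
#' month-day windows, inclusive at both ends; custom bounds with start after
#' end wrap the year boundary like the southern default.
#'
#' @param dates a `Date` vector.
#' @param zone `"north"` (default) or `"south"`; selects the conventional
#'   window when `fss`/`fse` are not given.
#' @param fss,fse optional Fire Season Start/End, either `Date`s (only the
#'   month and day are used) or `"MM-DD"` strings; both or neither.
#' @return Logical vector aligned with `dates`; `TRUE` for in-season days.
#'   Use `which()` on it to index the corresponding time slices.
#' @export
fire_season_mask <- function(dates, zone = c("north", "south"), fss = NULL,
                             fse = NULL) {
  dates <- as.Date(dates)
  b <- season_bounds(match.arg(zone), fss, fse)
  md <- as.integer(format(dates, "%m")) * 100L +
    as.integer(format(dates, "%d"))
  if (b$wrap) md >= b$start | md <= b$end else md >= b$start & md <= b$end
}

#' Season-year label of each date
#'
#' Groups dates into season-years for yearly statistics: for a non-wrapping
#' season this is the calendar year; a wrapping season (e.g. the southern
#' default, October--April) is labeled by the year containing its start, so
#' January days belong to the previous year's season.
#'
#' @inheritParams fire_season_mask
#' @return Integer vector of season-year labels aligned with `dates`.
#' @export
season_year <- function(dates, zone = c("north", "south"), fss = NULL,
                        fse = NULL) {
  dates <- as.Date(dates)
  b <- season_bounds(match.arg(zone), fss, fse)
  yr <- as.integer(format(dates, "%Y"))
  if (!b$wrap) return(yr)
  md <- as.integer(format(dates, "%m")) * 100L +
    as.integer(format(dates, "%d"))
  ifelse(md >= b$start, yr, yr - 1L)
}

# calendar length (days) of the season starting in season-year `year`
season_length_days <- function(year, zone = "north", fss = NULL, fse = NULL) {
  b <- season_bounds(zone, fss, fse)
  start <- as.Date(sprintf("%04d-%02d-%02d", year, b$start %/% 100L,
                           b$start %% 100L))
  end_year <- if (b$wrap) year + 1L else year
  end <- as.Date(sprintf("%04d-%02d-%02d", end_year, b$end %/% 100L,
                         b$end %% 100L))
  as.integer(end - start) + 1L
}
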