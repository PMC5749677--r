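# Small deterministic fixtures shared across the suite.

# cube with values 0, 1, 2, ... laid out [time, lat, lon]
counting_cube <- function(nt = 3, nlat = 2, nlon = 2,
                          start = as.Date("2000-01-01"),
                          lats = NULL, lons = NULL, units = "") {
  if (is.null(lats)) lats <- seq(50, by = -1, length.out = nlat)
  if (is.null(lons)) lons <- seq(0, by = 1, length.out = nlon)
  vals <- array(seq_len(nt * nlat * nlon) - 1, dim = c(nt, nlat, nlon))
  fire_cube(vals, start + seq_len(nt) - 1, lats, lons, units)
}

# independent percentile oracle: sort + linear interpolation with the k-th
# of n order statistics at cumulative fraction (k - 1) / (n - 1)
oracle_percentile <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# pooled quantile of a mixture of gamma distributions (equal-weight cells)
gamma_mixture_quantile <- function(p, shape, scales) {
  f <- function(x) mean(stats::pgamma(x, shape = shape, scale = scales)) - p
  stats::uniroot(f, c(1e-8, 1e6), tol = 1e-10)$root
}

# write a cube to a temp NetCDF file, returning its path
temp_nc <- function(cube, varname = "fwi", dir = tempdir()) {
  path <- tempfile("cube", tmpdir = dir, fileext = ".nc")
  write_cube(cube, path, varname)
  path
}

# gzip a file in place, producing path.gz (the original is kept)
gzip_file <- function(path) {
  out <- paste0(path, ".gz")
  con_in <- file(path, "rb")
  con_out <- gzfile(out, "wb")
  repeat {
    buf <- readBin(con_in, "raw", n = 2^20)
    if (length(buf) == 0) break
    writeBin(buf, con_out)
  }
  close(con_in)
  close(con_out)
  out
}

# subset a cube to the given time indices
cube_time_subset <- function(cube, idx) {
  fire_cube(cube$values[idx, , , drop = FALSE], cube$dates[idx],
            cube$lats, cube$lons, cube$units)
}

# restrict a cube to its (northern, by default) fire season
season_subset <- function(cube, zone = "north", fss = NULL, fse = NULL) {
  cube_time_subset(cube, which(fire_season_mask(cube$dates, zone, fss, fse)))
}
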