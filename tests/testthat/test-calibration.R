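# direct, independent evaluations of the published intensity equations
oracle_f2i <- function(fwi) exp(0.980 * log(fwi)^1.546) / 0.289
oracle_i2f <- function(i) exp(1.013 * log(0.289 * i)^0.647)

test_that("the FWI/intensity transforms match direct formula evaluation", {
  expect_equal(fwi_to_intensity(33), oracle_f2i(33))
  expect_equal(fwi_to_intensity(33), 3.07e3, tolerance = 0.01)
  expect_equal(fwi_to_intensity(10), 1.22e2, tolerance = 0.01)
  expect_equal(intensity_to_fwi(oracle_f2i(33)), 33, tolerance = 0.001)
  # limit of the forward formula as FWI -> 1+
  expect_equal(fwi_to_intensity(1 + 1e-9), 1 / 0.289, tolerance = 1e-6)
  # closed-form point of the inverse: I = e / 0.289 gives FWI = e^1.013
  expect_equal(intensity_to_fwi(exp(1) / 0.289), exp(1.013))
  expect_error(fwi_to_intensity(0.5), "exceed 1")
  expect_error(intensity_to_fwi(1), "exceed 1")
})

test_that("the transforms are near-inverses over the working range", {
  x <- seq(2, 120, length.out = 1000)
  back <- intensity_to_fwi(fwi_to_intensity(x))
  expect_lt(max(abs(back - x) / x), 0.01)
})

test_that("geometric progression in intensity produces the danger ladder", {
  lv <- danger_levels_from_extreme(33, calibration_config(ratio = 5))
  expect_equal(lv$thresholds, c(2, 5, 10, 19, 33))
  # unrounded thresholds map back to intensities in exact ratio r
  ints <- oracle_f2i(lv$raw_thresholds[-1])  # raw low value is outside Eq 1's
  ratios <- ints[-1] / ints[-length(ints)]   # precise round-trip domain
  expect_equal(ratios, rep(5, length(ratios)), tolerance = 0.02)
  # strictly increasing and anchored at the extreme
  expect_true(all(diff(lv$thresholds) > 0))
  expect_equal(lv$thresholds[5], round(lv$raw_thresholds[5]))
  expect_equal(lv$raw_thresholds[5], 33, tolerance = 0.001)
})

test_that("class ratios near 1 collapse the ladder toward the extreme", {
  lv <- danger_levels_from_extreme(33, calibration_config(
    ratio = 1.01, round_to_integer = FALSE))
  spread <- diff(range(lv$raw_thresholds)) / max(lv$raw_thresholds)
  expect_lt(spread, 0.02)  # total intensity span 1.01^4 ~ 4% squeezes FWI
  # too aggressive a ratio pushes the lowest class out of the domain
  expect_error(danger_levels_from_extreme(5, calibration_config(ratio = 50)),
               "smaller ratio")
  expect_error(danger_levels_from_extreme(0.5), "above 1")
})

test_that("the yearly extreme matches the sorting oracle on a single cell", {
  # one cell, one year: 200 in-season days holding values 1..200
  days <- seq.Date(as.Date("2013-04-01"), by = "day", length.out = 200)
  cube <- fire_cube(array(1:200, c(200, 1, 1)), days, 50, 0)
  cfg <- calibration_config(ndays = 4)
  got <- regional_yearly_extreme(cube, cfg)
  p <- 1 - 4 / 214  # northern season spans 214 calendar days
  expect_equal(got, oracle_percentile(1:200, p))
})

test_that("identical yearly distributions give that year's percentile back", {
  one_year <- function(y) {
    days <- seq.Date(as.Date(sprintf("%d-04-01", y)), by = "day",
                     length.out = 214)
    vals <- array(rep(seq(0.5, 50, length.out = 214), each = 1),
                  c(214, 1, 1))
    fire_cube(vals, days, 50, 0)
  }
  cubes <- lapply(2001:2005, one_year)
  big <- fire_cube(
    do.call(function(...) {
      a <- array(NA_real_, c(214 * 5, 1, 1))
      for (k in 1:5) a[(k - 1) * 214 + 1:214, , ] <- cubes[[k]]$values
      a
    }, list()),
    as.Date(unlist(lapply(cubes, `[[`, "dates")), origin = "1970-01-01"),
    50, 0)
  got <- regional_yearly_extreme(big)
  expect_equal(got, oracle_percentile(seq(0.5, 50, length.out = 214),
                                      1 - 4 / 214))
})

test_that("the extreme is monotone in ndays and order-free over cells", {
  spec <- sim_spec(n_lat = 4, n_lon = 4, years = 2001:2003,
                   seasonal_amplitude = 0, seed = 5)
  cube <- season_subset(make_fwi_cube(spec))
  e4 <- regional_yearly_extreme(cube, calibration_config(ndays = 4))
  e8 <- regional_yearly_extreme(cube, calibration_config(ndays = 8))
  expect_lte(e8, e4)
  # pooling ignores spatial order: permute the longitude columns
  perm <- c(3, 1, 4, 2)
  shuffled <- fire_cube(cube$values[, , perm], cube$dates, cube$lats,
                        sort(cube$lons[perm]), cube$units)
  expect_equal(regional_yearly_extreme(shuffled,
                                       calibration_config(ndays = 4)), e4)
})

test_that("empty years are skipped with a warning, all-empty is an error", {
  days <- c(seq.Date(as.Date("2013-05-01"), by = "day", length.out = 50),
            seq.Date(as.Date("2014-05-01"), by = "day", length.out = 50))
  vals <- array(stats::runif(100, 1, 30), c(100, 1, 1))
  vals[51:100, , ] <- NA
  cube <- fire_cube(vals, days, 50, 0)
  expect_warning(e <- regional_yearly_extreme(cube), "skipped")
  expect_true(is.finite(e))
  allna <- fire_cube(array(NA_real_, c(100, 1, 1)), days, 50, 0)
  expect_error(suppressWarnings(regional_yearly_extreme(allna)), "no valid")
})

test_that("end-to-end calibration recovers ordered thresholds by region", {
  spec <- sim_spec(n_lat = 8, n_lon = 8, years = 2001:2003, seed = 9)
  cube <- season_subset(make_fwi_cube(spec))
  # scale grows toward low latitudes: southern block runs hotter
  north_blk <- mask_crop_subset(cube, cells_region(cube, 1:3, 1:8, "cool"))
  south_blk <- mask_crop_subset(cube, cells_region(cube, 6:8, 1:8, "warm"))
  lv_n <- get_fire_danger_levels(north_blk, area_id = "cool")
  lv_s <- get_fire_danger_levels(south_blk, area_id = "warm")
  expect_true(all(lv_s$thresholds >= lv_n$thresholds))
  expect_gt(lv_s$extreme_fwi, lv_n$extreme_fwi)
})

test_that("classification assigns the six danger classes by half-open bins", {
  lv <- danger_levels_from_extreme(33)
  got <- classify_fwi(c(0.5, 1.9, 2, 4.9, 5, 9.9, 10, 18.9, 19, 32.9, 33, 80),
                      lv)
  expect_equal(as.character(got),
               rep(c("very low", "low", "moderate", "high", "very high",
                     "extreme"), each = 2))
  expect_true(is.na(classify_fwi(NA, lv)))
})

test_that("danger levels serialize to JSON and back faithfully", {
  lv <- danger_levels_from_extreme(33, area_id = "EURO")
  path <- tempfile(fileext = ".json")
  danger_levels_to_json(lv, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$thresholds, c(2, 5, 10, 19, 33))
  expect_equal(back$area_id, "EURO")
  expect_equal(back$config$ratio, 5)
})
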