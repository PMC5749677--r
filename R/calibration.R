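#' Calibration configuration
#'
#' Parameters controlling how danger-class thresholds are derived from an
#' FWI climatology.
#'
#' @param ndays expected number of fire days per year (default 4). Together
#'   with the fire-season length N it fixes the yearly percentile level
#'   p = 100 (1 - ndays / N); for the default northern season (214 days)
#'   and ndays = 4 this is about the 98th percentile.
#' @param ratio constant fire-intensity ratio between consecutive danger
#'   classes (default 5); must exceed 1.
#' @param n_thresholds number of class boundaries (default 5, separating six
#'   danger classes from very low to extreme).
#' @param round_to_integer round the published thresholds to the nearest
#'   integer (default `TRUE`); unrounded values are always retained.
#' @param pooling `"pooled"` (default) pools every valid cell-day of the
#'   region into one yearly sample; `"percell"` takes the yearly percentile
#'   cell by cell and uses the median across cells.
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(ndays = 4, ratio = 5, n_thresholds = 5,
                               round_to_integer = TRUE,
                               pooling = c("pooled", "percell")) {
  if (ndays <= 0) stop("ndays must be positive")
  if (ratio <= 1) stop("ratio must exceed 1")
  if (n_thresholds < 1) stop("n_thresholds must be at least 1")
  structure(list(ndays = ndays, ratio = ratio,
                 n_thresholds = as.integer(n_thresholds),
                 round_to_integer = isTRUE(round_to_integer),
                 pooling = match.arg(pooling)),
            class = "calibration_config")
}

#' Fire Weather Index to fire-line intensity
#'
#' The published exponential relationship linking the dimensionless FWI to
#' fire-line intensity I (kW/m scale):
#' `I = exp(0.980 (ln FWI)^1.546) / 0.289`.
#' Danger classes are spaced geometrically in I, not in FWI, because fire
#' severity grows exponentially with intensity.
#'
#' @param fwi numeric vector of FWI values, each > 1 (the transform needs a
#'   positive logarithm; the "very low" class below the first threshold
#'   never requires it).
#' @return Fire intensity values on the same length.
#' @seealso [intensity_to_fwi()], the published near-inverse.
#' @export
fwi_to_intensity <- function(fwi) {
  if (any(fwi <= 1)) stop("fwi must exceed 1 for the intensity transform")
  exp(0.980 * log(fwi)^1.546) / 0.289
}

#' Fire-line intensity back to Fire Weather Index
#'
#' The published inverse relationship
#' `FWI = exp(1.013 (ln(0.289 I))^0.647)`. The pair of published equations
#' are near-inverses of each other (round-trip error stays below 1 percent
#' over the working FWI range), not exact algebraic inverses.
#'
#' @param intensity numeric vector with `0.289 * intensity > 1`.
#' @return FWI values.
#' @export
intensity_to_fwi <- function(intensity) {
  if (any(0.289 * intensity <= 1)) {
    stop("0.289 * intensity must exceed 1 for the inverse transform")
  }
  exp(1.013 * log(0.289 * intensity)^0.647)
}

#' Calibrated extreme FWI of a region
#'
#' The anchor of the danger scale: per season-year, all valid cell-day FWI
#' values of the (already masked/cropped, fire-season) record are pooled and
#' the p-th percentile taken, with p = 100 (1 - ndays / N) where N is the
#' calendar length of that year's fire season; the extreme is the median of
#' these yearly percentiles. With the defaults (ndays = 4, 214-day northern
#' season) this is the median yearly ~98th percentile, i.e. the FWI exceeded
#' on about the ndays most severe days of a typical year.
#'
#' @param fire_index a [fire_cube()] already restricted to the region and
#'   fire season of interest (see [mask_crop_subset()] and
#'   [fire_season_mask()]).
#' @param config a [calibration_config()].
#' @param zone,fss,fse fire-season definition used to group dates into
#'   season-years and to fix each year's season length N; must match the
#'   subsetting applied to `fire_index`.
#' @return The extreme FWI (scalar).
#' @export
regional_yearly_extreme <- function(fire_index, config = calibration_config(),
                                    zone = c("north", "south"), fss = NULL,
                                    fse = NULL) {
  stopifnot(is_fire_cube(fire_index), inherits(config, "calibration_config"))
  zone <- match.arg(zone)
  yrs <- season_year(fire_index$dates, zone, fss, fse)
  flat <- matrix(fire_index$values, nrow = n_times(fire_index))
  yearly <- vapply(sort(unique(yrs)), function(y) {
    n_season <- season_length_days(y, zone, fss, fse)
    if (config$ndays >= n_season) {
      stop("ndays (", config$ndays, ") must be below the season length (",
           n_season, " days)")
    }
    p <- 1 - config$ndays / n_season
    rows <- flat[yrs == y, , drop = FALSE]
    if (config$pooling == "pooled") {
      x <- rows[!is.na(rows)]
      if (length(x) == 0) return(NA_real_)
      stats::quantile(x, p, names = FALSE)
    } else {
      per_cell <- apply(rows, 2, function(x) {
        x <- x[!is.na(x)]
        if (length(x) == 0) NA_real_ else stats::quantile(x, p, names = FALSE)
      })
      if (all(is.na(per_cell))) return(NA_real_)
      stats::median(per_cell, na.rm = TRUE)
    }
  }, numeric(1))
  if (anyNA(yearly)) {
    if (all(is.na(yearly))) stop("no valid values in any season-year")
    warning(sum(is.na(yearly)), " season-year(s) without valid values skipped")
    yearly <- yearly[!is.na(yearly)]
  }
  stats::median(yearly)
}

#' Danger-class thresholds from a calibrated extreme
#'
#' Places the class boundaries by geometric progression in fire intensity:
#' the extreme FWI is transformed to intensity ([fwi_to_intensity()]), the
#' intensity is divided repeatedly by the constant class ratio r, and each
#' intensity is transformed back to FWI ([intensity_to_fwi()]). With the
#' default five thresholds this yields the boundaries of the six danger
#' classes very low, low, moderate, high, very high and extreme.
#'
#' @param extreme_fwi calibrated extreme FWI (> 1), usually from
#'   [regional_yearly_extreme()].
#' @param config a [calibration_config()].
#' @param area_id label carried into the result.
#' @return An object of class `danger_levels` with fields `thresholds`
#'   (ascending, rounded when configured), `raw_thresholds`, `extreme_fwi`,
#'   `area_id` and `config`.
#' @export
danger_levels_from_extreme <- function(extreme_fwi,
                                       config = calibration_config(),
                                       area_id = "area") {
  stopifnot(inherits(config, "calibration_config"))
  if (length(extreme_fwi) != 1 || !is.finite(extreme_fwi) || extreme_fwi <= 1) {
    stop("extreme_fwi must be a single finite value above 1")
  }
  n <- config$n_thresholds
  i_top <- fwi_to_intensity(extreme_fwi)
  intensities <- i_top / config$ratio^((n - 1):0)
  if (any(0.289 * intensities <= 1)) {
    stop("lowest class intensity falls outside the transform domain; ",
         "use a smaller ratio or fewer thresholds")
  }
  raw <- intensity_to_fwi(intensities)
  thr <- if (config$round_to_integer) round(raw) else raw
  if (any(diff(thr) <= 0)) {
    stop("thresholds not strictly increasing after rounding; ",
         "set round_to_integer = FALSE or use a larger ratio")
  }
  structure(list(thresholds = as.numeric(thr), raw_thresholds = raw,
                 extreme_fwi = extreme_fwi, area_id = as.character(area_id),
                 config = config),
            class = "danger_levels")
}

#' Calibrate danger levels from an FWI record
#'
#' End-to-end calibration: computes the regional extreme with
#' [regional_yearly_extreme()] and converts it into class boundaries with
#' [danger_levels_from_extreme()]. The input cube must already be masked and
#' cropped to the area of interest and subset to fire-season dates; the
#' minimum usable area is a single grid cell.
#'
#' @inheritParams regional_yearly_extreme
#' @param area_id label carried into the result.
#' @return A `danger_levels` object.
#' @export
get_fire_danger_levels <- function(fire_index, config = calibration_config(),
                                   zone = c("north", "south"), fss = NULL,
                                   fse = NULL, area_id = "area") {
  extreme <- regional_yearly_extreme(fire_index, config, match.arg(zone),
                                     fss, fse)
  danger_levels_from_extreme(extreme, config, area_id)
}

danger_class_names <- c("very low", "low", "moderate", "high", "very high",
                        "extreme")

#' Classify FWI values into danger classes
#'
#' Assigns each value its danger class: below the first threshold is
#' "very low", at or above the last is "extreme", and value v falls in class
#' k when threshold_(k-1) <= v < threshold_k.
#'
#' @param fwi numeric vector (or array) of FWI values.
#' @param levels a `danger_levels` object (or a plain ascending threshold
#'   vector).
#' @return Factor of danger-class labels, `NA` where `fwi` is missing.
#' @export
classify_fwi <- function(fwi, levels) {
  thr <- if (inherits(levels, "danger_levels")) levels$thresholds else
    as.numeric(levels)
  labels <- if (length(thr) == 5) danger_class_names else
    paste0("class", seq_len(length(thr) + 1))
  cut(as.numeric(fwi), breaks = c(-Inf, thr, Inf), labels = labels,
      right = FALSE)
}

#' @export
print.danger_levels <- function(x, ...) {
  cat("<danger_levels> '", x$area_id, "' (extreme FWI ",
      format(x$extreme_fwi, digits = 4), ", ratio ", x$config$ratio,
      ", ndays ", x$config$ndays, ")\n", sep = "")
  labels <- if (length(x$thresholds) == 5) danger_class_names[-1] else
    paste0("class", seq_along(x$thresholds) + 1)
  for (i in seq_along(x$thresholds)) {
    cat(sprintf("  %-10s >= %-6s (raw %.3f)\n", labels[i],
                format(x$thresholds[i]), x$raw_thresholds[i]))
  }
  invisible(x)
}

#' Serialize danger levels to JSON
#'
#' @param x a `danger_levels` object.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return `path` (or the JSON string).
#' @export
danger_levels_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "danger_levels"))
  obj <- list(area_id = x$area_id, thresholds = x$thresholds,
              raw_thresholds = x$raw_thresholds,
              extreme_fwi = x$extreme_fwi,
              config = unclass(x$config))
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    path
  }
}
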