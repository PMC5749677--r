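#' Binarize a gridded field at a threshold
#'
#' Maps every value at or above the threshold to 1 and every value below it
#' to 0; missing cells stay missing. Used both for observations (e.g. "a
#' large fire burned at least 50 hectares in this cell today") and for the
#' fire index ("the index reached the high danger level").
#'
#' @param r a [fire_cube()] or [fire_grid()].
#' @param threshold finite numeric threshold.
#' @return Same class as `r` with values in \{0, 1\} (and `NA`).
#' @export
binarize_ge <- function(r, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  v <- ifelse(r$values >= threshold, 1, 0)
  if (is_fire_grid(r)) {
    fire_grid(matrix(v, nrow = nrow(r$values)), r$lats, r$lons, "binary")
  } else {
    fire_cube(array(v, dim(r$values)), r$dates, r$lats, r$lons, "binary")
  }
}

#' Pair fire-index predictions with burned-area observations
#'
#' Implements the verification pairing: observations are binarized at
#' `obs_threshold` (large fires only), the index at `fire_threshold`
#' (danger-level exceedance), the two records are matched on their common
#' dates, binary observations on a finer grid are brought onto the index
#' grid by nearest-neighbour resampling, and cells missing in either field
#' on a given day are dropped pairwise. The caller is responsible for
#' masking/cropping both inputs to the region of interest beforehand; the
#' record is deliberately not restricted to the fire season.
#'
#' @param fire_index [fire_cube()] of the daily fire-danger index.
#' @param observation [fire_cube()] of daily burned areas (hectares).
#' @param fire_threshold danger level whose exceedance counts as a
#'   prediction of fire-supporting conditions.
#' @param obs_threshold burned area (hectares) from which a fire counts as
#'   large (default 50).
#' @return An object of class `paired_samples`: binary vectors `pred` and
#'   `obs` plus `scores`, the raw index values aligned with `obs` (used for
#'   ROC analysis).
#' @export
validate_fire_danger_levels <- function(fire_index, observation,
                                        fire_threshold, obs_threshold = 50) {
  stopifnot(is_fire_cube(fire_index), is_fire_cube(observation))
  common <- as.Date(intersect(fire_index$dates, observation$dates),
                    origin = "1970-01-01")
  if (length(common) == 0) {
    stop("fire index and observations share no dates")
  }
  i_idx <- match(common, fire_index$dates)
  i_obs <- match(common, observation$dates)
  obs_bin <- binarize_ge(observation, obs_threshold)
  same_grid <- length(observation$lats) == length(fire_index$lats) &&
    length(observation$lons) == length(fire_index$lons) &&
    isTRUE(all.equal(observation$lats, fire_index$lats)) &&
    isTRUE(all.equal(observation$lons, fire_index$lons))
  if (!same_grid) {
    obs_bin <- resample_nearest(obs_bin, fire_index$lats, fire_index$lons)
  }
  pred_bin <- binarize_ge(fire_index, fire_threshold)
  scores <- as.vector(fire_index$values[i_idx, , , drop = FALSE])
  pred <- as.vector(pred_bin$values[i_idx, , , drop = FALSE])
  obs <- as.vector(obs_bin$values[i_obs, , , drop = FALSE])
  keep <- !is.na(pred) & !is.na(obs)
  structure(list(pred = pred[keep], obs = obs[keep], scores = scores[keep]),
            class = "paired_samples")
}

#' Contingency table of paired binary samples
#'
#' Cross-tabulates predictions against observations into hits (both 1),
#' misses (observed 1, predicted 0), false alarms (predicted 1, observed 0)
#' and correct negatives (both 0); the four counts always sum to the number
#' of paired samples. The probability of detection is attached when there is
#' at least one observed event.
#'
#' @param s a `paired_samples` object (or any list with binary `pred` and
#'   `obs` of equal length).
#' @return An object of class `contingency` with fields `hits`, `misses`,
#'   `false_alarms`, `correct_negatives`, `n` and `pod`.
#' @export
contingency_table <- function(s) {
  pred <- as.numeric(s$pred)
  obs <- as.numeric(s$obs)
  if (length(pred) == 0) stop("no paired samples")
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  if (!all(pred %in% c(0, 1)) || !all(obs %in% c(0, 1))) {
    stop("pred and obs must be binary")
  }
  out <- structure(list(
    hits = sum(pred == 1 & obs == 1),
    misses = sum(pred == 0 & obs == 1),
    false_alarms = sum(pred == 1 & obs == 0),
    correct_negatives = sum(pred == 0 & obs == 0),
    n = length(pred)
  ), class = "contingency")
  out$pod <- probability_of_detection(out)
  out
}

#' Probability of detection
#'
#' The fraction of observed events that were predicted, reported as a
#' percentage with the conventional two-decimal rounding applied to the
#' fraction before scaling: `round(hits / (hits + misses), 2) * 100`.
#'
#' @param x a `contingency` object, or the number of hits when `misses` is
#'   given.
#' @param misses number of misses (when `x` is a hit count).
#' @return POD percentage; `NA` when no event was observed.
#' @export
probability_of_detection <- function(x, misses = NULL) {
  if (inherits(x, "contingency")) {
    hits <- x$hits
    misses <- x$misses
  } else {
    if (is.null(misses)) stop("misses must be supplied with a hit count")
    hits <- x
  }
  if (hits + misses == 0) return(NA_real_)
  round(hits / (hits + misses), 2) * 100
}

#' @export
print.contingency <- function(x, ...) {
  cat("<contingency> n =", x$n, "\n")
  cat(sprintf("  hits %d | misses %d | false alarms %d | correct negatives %d\n",
              x$hits, x$misses, x$false_alarms, x$correct_negatives))
  cat("  POD:", if (is.na(x$pod)) "undefined (no observed events)" else
    paste0(x$pod, "%"), "\n")
  invisible(x)
}

#' ROC curve and AUC of index scores against binary observations
#'
#' Builds the receiver operating characteristic by sweeping the decision
#' threshold over every distinct score and computes the area under the
#' curve with the rank (Mann-Whitney) statistic, ties handled by midranks.
#' AUC 0.5 means the index carries no information about fire occurrence;
#' 1 means perfect separation.
#'
#' @param scores numeric vector of raw index values.
#' @param obs binary vector (1 = large fire observed) aligned with
#'   `scores`.
#' @return An object of class `roc_result`: `curve`, a data frame with
#'   columns `threshold`, `far` (false-alarm rate) and `hr` (hit rate)
#'   ordered from the strictest threshold to the laxest, and scalar `auc`.
#' @export
roc_curve_auc <- function(scores, obs) {
  obs <- as.numeric(obs)
  keep <- !is.na(scores) & !is.na(obs)
  scores <- scores[keep]
  obs <- obs[keep]
  if (!all(obs %in% c(0, 1))) stop("obs must be binary")
  n1 <- sum(obs == 1)
  n0 <- sum(obs == 0)
  if (n1 == 0 || n0 == 0) {
    stop("obs must contain both classes for a ROC analysis")
  }
  r <- rank(scores)  # midranks for ties
  auc <- (sum(r[obs == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  o_sorted <- obs[ord]
  # collapse tied scores so each distinct value is one operating point
  last_of_run <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  tp <- cumsum(o_sorted)[last_of_run]
  fp <- cumsum(1 - o_sorted)[last_of_run]
  curve <- data.frame(
    threshold = c(Inf, s_sorted[last_of_run]),
    far = c(0, fp / n0),
    hr = c(0, tp / n1)
  )
  structure(list(curve = curve, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC =", format(x$auc, digits = 4), "over",
      nrow(x$curve) - 1, "operating points\n")
  invisible(x)
}

#' Sum contingency tables across areas
#'
#' Aggregates per-area verification into an "area as the sum of its parts"
#' total by summing the four counts; the POD is recomputed from the summed
#' hits and misses.
#'
#' @param ... `contingency` objects (or one list of them).
#' @return A `contingency` object with summed counts.
#' @export
sum_contingency <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && !inherits(parts[[1]], "contingency")) {
    parts <- parts[[1]]
  }
  stopifnot(all(vapply(parts, inherits, logical(1), "contingency")))
  tot <- structure(list(
    hits = sum(vapply(parts, `[[`, numeric(1), "hits")),
    misses = sum(vapply(parts, `[[`, numeric(1), "misses")),
    false_alarms = sum(vapply(parts, `[[`, numeric(1), "false_alarms")),
    correct_negatives = sum(vapply(parts, `[[`, numeric(1),
                                   "correct_negatives")),
    n = sum(vapply(parts, `[[`, numeric(1), "n"))
  ), class = "contingency")
  tot$pod <- probability_of_detection(tot)
  tot
}
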