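test_that("binarization is >= at the threshold and keeps missing missing", {
  cube <- fire_cube(array(c(50, 49.9, NA, 75), c(1, 2, 2)),
                    as.Date("2003-01-01"), c(51, 50), c(0, 1))
  b <- binarize_ge(cube, 50)
  expect_equal(b$values[1, 1, 1], 1)   # exactly at threshold counts
  expect_equal(b$values[1, 2, 1], 0)
  expect_true(is.na(b$values[1, 1, 2]))
  expect_equal(b$values[1, 2, 2], 1)
  allna <- fire_cube(array(NA_real_, c(1, 2, 2)), as.Date("2003-01-01"),
                     c(51, 50), c(0, 1))
  expect_true(all(is.na(binarize_ge(allna, 50)$values)))
  expect_error(binarize_ge(cube, Inf), "finite")
})

test_that("hand-built toy cubes pair exactly as exhaustive enumeration says", {
  dates <- as.Date("2003-07-01") + 0:1
  lats <- c(46, 45)
  lons <- c(8, 9)
  fwi_vals <- array(c(25, 5, 12, 30,   9, 22, 3, 40), c(2, 2, 2))
  ba_vals <- array(c(60, 0, 10, 55,   0, 100, NA, 20), c(2, 2, 2))
  fwi <- fire_cube(aperm(array(fwi_vals, c(2, 2, 2)), c(1, 2, 3)), dates,
                   lats, lons)
  ba <- fire_cube(ba_vals, dates, lats, lons, "hectares")
  pairs <- validate_fire_danger_levels(fwi, ba, fire_threshold = 20,
                                       obs_threshold = 50)
  # brute-force enumeration over every (date, cell)
  exp_pred <- exp_obs <- exp_scores <- c()
  for (t in 1:2) for (i in 1:2) for (j in 1:2) {
    f <- fwi$values[t, i, j]
    o <- ba$values[t, i, j]
    if (is.na(f) || is.na(o)) next
    exp_pred <- c(exp_pred, as.numeric(f >= 20))
    exp_obs <- c(exp_obs, as.numeric(o >= 50))
    exp_scores <- c(exp_scores, f)
  }
  expect_setequal(paste(pairs$pred, pairs$obs, pairs$scores),
                  paste(exp_pred, exp_obs, exp_scores))
  expect_length(pairs$pred, 7)  # one pair lost to the NA observation
  ct <- contingency_table(pairs)
  expect_equal(ct$hits, sum(exp_pred == 1 & exp_obs == 1))
  expect_equal(ct$misses, sum(exp_pred == 0 & exp_obs == 1))
  expect_equal(ct$n, 7)
})

test_that("finer constant observations resample to all-ones predictand", {
  dates <- as.Date("2003-07-01") + 0:2
  fwi <- counting_cube(nt = 3, nlat = 2, nlon = 2,
                       start = dates[1],
                       lats = c(46, 45), lons = c(8, 9))
  fine_lats <- seq(46.25, by = -0.5, length.out = 4)
  fine_lons <- seq(7.75, by = 0.5, length.out = 4)
  ba <- fire_cube(array(100, c(3, 4, 4)), dates, fine_lats, fine_lons,
                  "hectares")
  pairs <- validate_fire_danger_levels(fwi, ba, 5, 50)
  expect_true(all(pairs$obs == 1))
  expect_length(pairs$obs, 12)
})

test_that("date handling: intersection drives pairing, disjoint errors", {
  a <- counting_cube(nt = 4, start = as.Date("2003-01-01"))
  b <- counting_cube(nt = 4, start = as.Date("2003-01-03"), units = "hectares")
  pairs <- validate_fire_danger_levels(a, b, 5, 5)
  expect_length(pairs$pred, 2 * 4)  # two overlapping days on a 2x2 grid
  late <- counting_cube(nt = 2, start = as.Date("2010-01-01"))
  expect_error(validate_fire_danger_levels(a, late, 5, 5), "no dates")
})

test_that("contingency counts cover the 2x2 cases and always conserve n", {
  ct <- contingency_table(list(pred = c(1, 1, 0, 0), obs = c(1, 0, 1, 0)))
  expect_equal(ct$hits, 1)
  expect_equal(ct$false_alarms, 1)
  expect_equal(ct$misses, 1)
  expect_equal(ct$correct_negatives, 1)
  all_hit <- contingency_table(list(pred = rep(1, 5), obs = rep(1, 5)))
  expect_equal(all_hit$hits, 5)
  expect_equal(all_hit$misses + all_hit$false_alarms +
                 all_hit$correct_negatives, 0)
  set.seed(3)
  s <- list(pred = stats::rbinom(1000, 1, 0.3),
            obs = stats::rbinom(1000, 1, 0.1))
  ct2 <- contingency_table(s)
  expect_equal(ct2$hits + ct2$misses + ct2$false_alarms +
                 ct2$correct_negatives, 1000)
  expect_error(contingency_table(list(pred = numeric(0), obs = numeric(0))),
               "no paired")
  expect_error(contingency_table(list(pred = c(1, 2), obs = c(0, 1))),
               "binary")
})

test_that("POD applies the round-then-scale convention", {
  expect_equal(probability_of_detection(10421, 5508), 65)
  expect_equal(probability_of_detection(0, 5), 0)
  expect_equal(probability_of_detection(7, 7), 50)
  expect_true(is.na(probability_of_detection(0, 0)))
  ct <- contingency_table(list(pred = c(1, 0, 1), obs = c(1, 1, 0)))
  expect_equal(probability_of_detection(ct), 50)
  expect_equal(ct$pod, 50)
})

test_that("POD is monotone non-increasing in the fire threshold", {
  spec <- sim_spec(n_lat = 6, n_lon = 6, years = 2003, obs_factor = 1,
                   seed = 21)
  fwi <- make_fwi_cube(spec)
  ba <- make_burned_area_cube(fwi, spec)
  pods <- vapply(c(2, 5, 10, 19, 33), function(thr) {
    ct <- contingency_table(validate_fire_danger_levels(fwi, ba, thr, 50))
    ct$pod
  }, numeric(1))
  expect_true(all(diff(pods) <= 0))
})

test_that("ROC/AUC agree with pairwise concordance and pROC on toy data", {
  # perfectly separating scores
  sep <- roc_curve_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$auc, 1)
  # 6-point set with a tie, hand-checked by pairwise concordance counting:
  # pairs (pos > neg) + 0.5 (ties) over n1 * n0
  scores <- c(3, 1, 4, 4, 2, 8)
  obs <- c(0, 0, 1, 0, 1, 1)
  pos <- scores[obs == 1]
  neg <- scores[obs == 0]
  conc <- 0
  for (p in pos) for (q in neg) conc <- conc + (p > q) + 0.5 * (p == q)
  expect_equal(roc_curve_auc(scores, obs)$auc, conc / (length(pos) *
                                                         length(neg)))
  set.seed(17)
  s <- stats::rnorm(500)
  o <- stats::rbinom(500, 1, stats::plogis(s))
  expect_equal(roc_curve_auc(s, o)$auc,
               as.numeric(pROC::auc(pROC::roc(o, s, quiet = TRUE))))
})

test_that("the ROC curve sweeps thresholds from strict to lax", {
  set.seed(19)
  s <- stats::rnorm(200)
  o <- stats::rbinom(200, 1, stats::plogis(2 * s))
  roc <- roc_curve_auc(s, o)
  expect_equal(roc$curve$far[1], 0)
  expect_equal(roc$curve$hr[1], 0)
  expect_equal(roc$curve$far[nrow(roc$curve)], 1)
  expect_equal(roc$curve$hr[nrow(roc$curve)], 1)
  expect_true(all(diff(roc$curve$far) >= 0))
  expect_true(all(diff(roc$curve$hr) >= 0))
  # AUC invariant under strictly increasing transforms of the score
  expect_equal(roc_curve_auc(exp(s), o)$auc, roc$auc)
  expect_error(roc_curve_auc(s, rep(1, 200)), "both classes")
})

test_that("summing per-area tables reproduces the pooled counts", {
  set.seed(23)
  mk <- function(n) list(pred = stats::rbinom(n, 1, 0.4),
                         obs = stats::rbinom(n, 1, 0.2))
  parts <- lapply(c(50, 80, 120), function(n) contingency_table(mk(n)))
  tot <- sum_contingency(parts)
  expect_equal(tot$n, 250)
  expect_equal(tot$hits, sum(vapply(parts, `[[`, numeric(1), "hits")))
  expect_equal(tot$pod, probability_of_detection(tot$hits, tot$misses))
})
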