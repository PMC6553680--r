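classified <- function(peak_s, pt, nb, a2 = 8) {
  classify_events(make_event_table(peak_s, pt, nb), threshold_model("linear", a2))
}

test_that("confusion counts follow the matching definitions", {
  # 3 manual peaks inside 3 distinct included events, 1 unmatched excluded
  ev <- classified(c(1, 2, 3, 4), pt = c(50, 50, 50, 10), nb = 2)
  cc <- match_events(c(1, 2, 3), ev)
  expect_equal(c(cc$tp, cc$fp, cc$fn, cc$tn), c(3, 0, 0, 1))
  expect_equal(cc$sensitivity, 1)
  expect_equal(cc$specificity, 1)

  # a manual peak inside no event is a false negative
  cc2 <- match_events(10, ev)
  expect_equal(cc2$fn, 1)
  expect_equal(cc2$fp, 3)

  # a manual peak inside an excluded event: a false negative, and that
  # event no longer counts as a true negative
  cc3 <- match_events(4, ev)
  expect_equal(c(cc3$tp, cc3$fn, cc3$tn), c(0, 1, 0))

  # two peaks in one included event: one matches, the other is unmatched
  cc4 <- match_events(c(0.999, 1.001), ev)
  expect_equal(c(cc4$tp, cc4$fn), c(1, 1))

  # zero manual FPs: sensitivity undefined and flagged
  cc5 <- match_events(numeric(0), ev)
  expect_true(is.na(cc5$sensitivity))
  expect_true(cc5$undefined[["sensitivity"]])

  # overlapping events are rejected
  bad <- classified(c(1, 1.004), pt = 50, nb = 2)
  expect_error(match_events(1, bad), "overlap")
})

test_that("matching agrees with the brute-force accounting oracle", {
  set.seed(61)
  for (rep_i in 1:25) {
    n <- sample(5:20, 1)
    ev <- classified(seq_len(n) + runif(n, 0, 0.4),
                     pt = runif(n, 10, 60), nb = runif(n, 1, 5))
    peaks <- runif(sample(0:6, 1), 0, n + 1)
    got <- match_events(peaks, ev)
    want <- brute_confusion(peaks, ev)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fp, want$fp)
    expect_equal(got$fn, want$fn)
    expect_equal(got$tn, want$tn)
  }
})

test_that("a perfectly separable corpus gives a saturated curve and AUC 100", {
  corpus <- lapply(1:4, function(i) {
    ev <- make_event_table(seq(1, 20), pt_amp_uV = rep(c(100, 4), 10),
                           noise_band_uV = 1)
    list(events = ev, peaks = seq(1, 20)[rep(c(TRUE, FALSE), 10)])
  })
  roc <- roc_curve(corpus, "linear", thresholds = c(14, 8, 5))
  expect_true(all(roc$table$sensitivity == 1))
  expect_true(all(roc$table$specificity == 1))
  expect_equal(roc$auc_pct, 100)
  expect_equal(optimal_threshold(roc), 5) # ties resolve to the smaller value
})

test_that("random annotations drive the AUC toward chance", {
  set.seed(62)
  aucs <- vapply(1:10, function(s) {
    corpus <- lapply(1:6, function(i) {
      n <- 40
      ev <- make_event_table(seq_len(n), pt_amp_uV = runif(n, 1, 16),
                             noise_band_uV = 1)
      # annotate HALF the events at random, ignoring amplitude
      list(events = ev, peaks = sort(sample(seq_len(n), n / 2)))
    })
    suppressMessages(roc_curve(corpus, "linear",
                               thresholds = c(14, 12, 10, 8, 6, 4, 2))$auc_pct)
  }, numeric(1))
  expect_equal(mean(aucs), 50, tolerance = 0.12)
})

test_that("the optimal threshold minimises the distance to the ideal point", {
  roc <- structure(list(table = data.frame(threshold = c(8, 4),
                                           sensitivity = c(0.9, 0.99),
                                           specificity = c(0.9, 0.8))),
                   class = "roc_curve")
  # distances: sqrt(0.1^2 + 0.1^2) = 0.141 < sqrt(0.2^2 + 0.01^2) = 0.200
  expect_equal(optimal_threshold(roc), 8)
  one <- structure(list(table = data.frame(threshold = 7, sensitivity = 0.5,
                                           specificity = 0.5)),
                   class = "roc_curve")
  expect_equal(optimal_threshold(one), 7)
})

test_that("cross-validation recovers the constructed optimal coefficient", {
  corpus <- constructed_event_corpus(n_rec = 10, seed = 63)
  cv <- cross_validate(corpus, k = 5, repeats = 20, seed = 7)
  expect_true(cv$modal_a2 %in% c(7, 8))
  expect_true(all(cv$folds$fold %in% 1:5))
  # folds partition the corpus each repeat
  expect_equal(unname(table(cv$folds$repeat_i)), rep(5L, 20L),
               ignore_attr = TRUE)
})

test_that("cross-validation is reproducible and degenerate on identical folds", {
  corpus <- constructed_event_corpus(n_rec = 6, seed = 64)
  cv1 <- cross_validate(corpus, k = 3, repeats = 5, seed = 11)
  cv2 <- cross_validate(corpus, k = 3, repeats = 5, seed = 11)
  expect_identical(cv1$folds, cv2$folds)
  # identical recordings in every fold: zero variance across folds
  same <- rep(corpus[1], 6)
  cv3 <- cross_validate(same, k = 3, repeats = 4, seed = 2)
  expect_equal(sd(cv3$folds$accuracy), 0)
  expect_error(cross_validate(corpus, k = 7, repeats = 1, seed = 1), "folds")
})

test_that("weighted least squares recovers exact and degenerate fits", {
  x <- c(1, 2, 4, 6, 8)
  f <- wls_fit(x, 11 * x)
  expect_equal(f$slope, 11, tolerance = 1e-10)
  expect_equal(f$intercept, 0, tolerance = 1e-10)
  expect_equal(f$r2, 1)
  expect_equal(f$slope_origin, 11, tolerance = 1e-10)
  expect_true(f$slope_ci[1] <= f$slope && f$slope <= f$slope_ci[2])

  two <- wls_fit(c(1, 2), c(5, 9))
  expect_equal(two$slope, 4)
  expect_equal(two$r2, 1)
  expect_false(two$ci_defined)
  expect_true(all(is.na(two$slope_ci)))

  expect_error(wls_fit(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  expect_error(wls_fit(c(-1, 2, 3), c(1, 2, 3)), "positive")
  # two-stage weighting also runs
  set.seed(65)
  x2 <- runif(50, 1, 10)
  f2 <- wls_fit(x2, 11 * x2 + rnorm(50, sd = x2), weights = "two_stage")
  expect_equal(f2$slope, 11, tolerance = 0.2)
})

test_that("the threshold scan returns the lowest count-matching value", {
  ev <- make_event_table(1:5, pt_amp_uV = c(10, 20, 30, 40, 50),
                         noise_band_uV = 1)
  # exhaustive-scan oracle over the same grid
  oracle <- function(manual) {
    for (t in seq(0, 51)) {
      if (abs(sum(ev$pt_amp_uV > t) - manual) <= 1) return(t)
    }
    NA_real_
  }
  for (manual in 0:6) {
    got <- optimal_atinc_search(ev, manual)
    expect_equal(got$at_inc_uV, oracle(manual))
  }
  # manual count == total events: threshold 0 already matches
  expect_equal(optimal_atinc_search(ev, 5)$at_inc_uV, 0)
  # a count gap larger than +/-1 is flagged absent
  gap <- make_event_table(1:4, pt_amp_uV = c(10, 10, 10, 10), noise_band_uV = 1)
  res <- optimal_atinc_search(gap, 2)
  expect_true(res$absent)
  expect_true(is.na(res$at_inc_uV))
})
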