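# Validation machinery: manual/automated event matching into confusion
# counts, median ROC curves with AUC, closest-to-[0,1] threshold selection,
# repeated k-fold cross-validation of the linear coefficient, weighted
# least-squares noise-vs-threshold regression, and the search for the
# lowest inclusion threshold reproducing a manual count.

# default threshold grids for the two model families
default_thresholds <- function(kind) {
  switch(kind,
         linear = c(14, 12, 10, 9, 8, 7, 6, 5, 4, 2),
         constant = c(100, 60, 40, 35, 30, 25, 20, 15, 10, 5))
}

#' Match manual FP annotations against detected events
#'
#' A manual peak matches an event when it lies within the event's
#' `[onset_s, offset_s)` interval; events are disjoint, so each peak sits in
#' at most one event.  Matching is one-to-one and greedy in time order (a
#' second peak inside an already-matched event goes unmatched).  Counts:
#' true positives are included (`"fp"`-labelled) events matched to a manual
#' peak; false positives are included events without one; false negatives
#' are manual peaks not matched to an included event; true negatives are
#' excluded (`"subthreshold"`) events containing no manual peak.  Block and
#' voluntary-train exclusions must be disabled for this comparison.
#'
#' @param manual_peaks_s numeric vector of manual FP peak times (s).
#' @param events classified event data frame with labels `"fp"` /
#'   `"subthreshold"` only.
#' @return object of class `confusion_counts`: `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity`, `accuracy` (each `NA` and flagged in
#'   `undefined` when its denominator is 0).
#' @export
match_events <- function(manual_peaks_s, events) {
  if (any(!events$label %in% c("fp", "subthreshold"))) {
    stop("disable block/voluntary exclusions before matching", call. = FALSE)
  }
  ev <- events[order(events$onset_s), , drop = FALSE]
  n_ev <- nrow(ev)
  if (n_ev > 1L && any(ev$onset_s[-1L] < ev$offset_s[-n_ev] - 1e-12)) {
    stop("events overlap; matching requires a disjoint stream", call. = FALSE)
  }
  pk <- sort(manual_peaks_s)
  hit <- rep(NA_integer_, length(pk))
  if (n_ev && length(pk)) {
    cand <- findInterval(pk, ev$onset_s)
    inside <- cand >= 1L & pk < ev$offset_s[pmax(cand, 1L)]
    hit[inside] <- cand[inside]
    hit[duplicated(hit, incomparables = NA)] <- NA_integer_  # greedy one-to-one
  }
  included <- which(ev$label == "fp")
  tp <- sum(hit %in% included)
  fp <- length(included) - tp
  fn <- length(pk) - tp
  contains_peak <- logical(n_ev)
  if (n_ev && length(pk)) {
    cand <- findInterval(pk, ev$onset_s)
    ok <- cand >= 1L & pk < ev$offset_s[pmax(cand, 1L)]
    contains_peak[unique(cand[ok])] <- TRUE
  }
  tn <- sum(ev$label == "subthreshold" & !contains_peak)
  confusion_counts(tp, fp, fn, tn)
}

confusion_counts <- function(tp, fp, fn, tn) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tot <- tp + fp + fn + tn
  acc <- if (tot > 0) (tp + tn) / tot else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 undefined = c(sensitivity = is.na(sens),
                               specificity = is.na(spec))),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: tp %d, fp %d, fn %d, tn %d (sens %.3f, spec %.3f)\n",
              x$tp, x$fp, x$fn, x$tn, x$sensitivity, x$specificity))
  invisible(x)
}

# per-recording x per-threshold confusion table; corpus elements are
# list(events = unclassified event df, peaks = manual peak times)
confusion_grid <- function(corpus, model_kind, thresholds) {
  n_rec <- length(corpus)
  n_thr <- length(thresholds)
  arr <- array(NA_real_, dim = c(n_rec, n_thr, 6L),
               dimnames = list(NULL, NULL,
                               c("tp", "fp", "fn", "tn", "sens", "spec")))
  for (r in seq_len(n_rec)) {
    for (t in seq_len(n_thr)) {
      cls <- classify_events(corpus[[r]]$events,
                             threshold_model(model_kind, thresholds[t]))
      cc <- match_events(corpus[[r]]$peaks, cls)
      arr[r, t, ] <- c(cc$tp, cc$fp, cc$fn, cc$tn, cc$sensitivity,
                       cc$specificity)
    }
  }
  arr
}

roc_auc_pct <- function(sens, spec) {
  x <- c(0, 1 - spec, 1)
  y <- c(0, sens, 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  100 * sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Median ROC curve across a corpus of annotated recordings
#'
#' For each threshold in the grid, every recording is classified and its
#' sensitivity/specificity computed by [match_events()]; the curve reports
#' the medians across recordings.  A recording with no manual FPs has an
#' undefined sensitivity and is dropped from that median (with a message).
#' The AUC is the trapezoidal area in (1 - specificity, sensitivity) space
#' with the curve anchored at (0,0) and (1,1), reported in percent.
#'
#' @param corpus list of recordings, each a list with `events` (an
#'   unclassified super-channel event data frame) and `peaks` (manual peak
#'   times in seconds).
#' @param model_kind `"linear"` or `"constant"`.
#' @param thresholds coefficient grid; defaults to the standard grids
#'   (A2: 14, 12, 10, 9, 8, 7, 6, 5, 4, 2; A1: 100, 60, 40, 35, 30, 25, 20,
#'   15, 10, 5).
#' @return object of class `roc_curve`: `table` (threshold, median
#'   sensitivity/specificity), `auc_pct`, and the per-recording `sens_mat` /
#'   `spec_mat` distributions.
#' @export
roc_curve <- function(corpus, model_kind = c("linear", "constant"),
                      thresholds = NULL) {
  model_kind <- match.arg(model_kind)
  if (length(corpus) < 2L) stop("need at least 2 recordings", call. = FALSE)
  if (is.null(thresholds)) thresholds <- default_thresholds(model_kind)
  stopifnot(all(thresholds > 0))
  arr <- confusion_grid(corpus, model_kind, thresholds)
  if (anyNA(arr[, 1L, "sens"])) {
    message(sum(is.na(arr[, 1L, "sens"])),
            " recording(s) without manual FPs dropped from sensitivity medians")
  }
  sens <- apply(arr[, , "sens", drop = FALSE], 2L, stats::median, na.rm = TRUE)
  spec <- apply(arr[, , "spec", drop = FALSE], 2L, stats::median, na.rm = TRUE)
  structure(list(table = data.frame(threshold = thresholds,
                                    sensitivity = sens, specificity = spec),
                 auc_pct = roc_auc_pct(sens, spec),
                 sens_mat = arr[, , "sens", drop = TRUE],
                 spec_mat = arr[, , "spec", drop = TRUE],
                 model_kind = model_kind, thresholds = thresholds),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve (%s model): %d thresholds, AUC %.1f%%\n",
              x$model_kind, nrow(x$table), x$auc_pct))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Threshold closest to the ideal operating point
#'
#' Returns the threshold whose median operating point minimises the
#' Euclidean distance from (1 - specificity, sensitivity) to the ideal
#' (0, 1); ties go to the smaller threshold.
#'
#' @param roc a [roc_curve()] result.
#' @return the selected threshold value.
#' @export
optimal_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"), nrow(roc$table) >= 1L)
  with(roc$table, {
    d <- sqrt((1 - specificity)^2 + (1 - sensitivity)^2)
    cand <- threshold[d == min(d)]
    min(cand)
  })
}

#' Repeated k-fold cross-validation of the linear coefficient
#'
#' Recordings are shuffled (seeded) into `k` folds; on each training fold
#' the candidate coefficient minimising the distance to the ideal operating
#' point of the training median ROC is selected, then evaluated on the test
#' fold with confusion counts pooled over its recordings (accuracy =
#' (tp + tn) / total).  Aggregates are means with standard errors grouped by
#' selected coefficient, plus the modal coefficient and its fold fraction.
#'
#' @param corpus as in [roc_curve()].
#' @param candidate_a2 coefficient grid (default the standard A2 grid).
#' @param k number of folds (default 5).
#' @param repeats number of repeats (default 100).
#' @param seed integer seed fixing the fold shuffles.
#' @param model_kind model family being cross-validated.
#' @return object of class `cv_result`: `folds` (per repeat x fold: selected
#'   coefficient, test accuracy/sensitivity/specificity), `by_a2`
#'   aggregates, `modal_a2`, `modal_fraction`.
#' @export
cross_validate <- function(corpus, candidate_a2 = default_thresholds("linear"),
                           k = 5, repeats = 100, seed = 1,
                           model_kind = "linear") {
  n <- length(corpus)
  if (n < k) stop("fewer recordings than folds", call. = FALSE)
  arr <- confusion_grid(corpus, model_kind, candidate_a2)
  if (anyNA(arr[, 1L, "sens"])) {
    message("fold evaluation: some recordings lack manual FPs; ",
            "their sensitivity is dropped from training medians")
  }
  set.seed(seed)
  rows <- vector("list", repeats * k)
  ri <- 0L
  for (rep_i in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(k), n))
    for (f in seq_len(k)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      sens <- apply(arr[tr, , "sens", drop = FALSE], 2L, stats::median, na.rm = TRUE)
      spec <- apply(arr[tr, , "spec", drop = FALSE], 2L, stats::median, na.rm = TRUE)
      d <- sqrt((1 - spec)^2 + (1 - sens)^2)
      sel <- which(d == min(d))
      sel <- sel[which.min(candidate_a2[sel])]
      tp <- sum(arr[te, sel, "tp"]); fp <- sum(arr[te, sel, "fp"])
      fn <- sum(arr[te, sel, "fn"]); tn <- sum(arr[te, sel, "tn"])
      cc <- confusion_counts(tp, fp, fn, tn)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(repeat_i = rep_i, fold = f,
                               a2 = candidate_a2[sel],
                               accuracy = cc$accuracy,
                               sensitivity = cc$sensitivity,
                               specificity = cc$specificity)
    }
  }
  folds <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(folds, folds$a2), function(g) {
    data.frame(a2 = g$a2[1L], n_folds = nrow(g),
               fraction = nrow(g) / nrow(folds),
               accuracy_mean = mean(g$accuracy), accuracy_sem = sem(g$accuracy),
               sensitivity_mean = mean(g$sensitivity, na.rm = TRUE),
               sensitivity_sem = sem(g$sensitivity[!is.na(g$sensitivity)]),
               specificity_mean = mean(g$specificity, na.rm = TRUE),
               specificity_sem = sem(g$specificity[!is.na(g$specificity)]))
  }))
  rownames(agg) <- NULL
  modal <- agg$a2[which.max(agg$n_folds)]
  structure(list(folds = folds, by_a2 = agg, modal_a2 = modal,
                 modal_fraction = agg$fraction[agg$a2 == modal],
                 k = k, repeats = repeats, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d repeats of %d-fold CV; modal coefficient %g (%.1f%% of folds)\n",
              x$repeats, x$k, x$modal_a2, 100 * x$modal_fraction))
  print(x$by_a2, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Weighted least-squares fit of threshold against noise band
#'
#' Fits `y ~ x` by weighted least squares for heteroscedastic data whose
#' scatter grows with the noise band; the default weights are proportional
#' to `1/x^2` (residual SD assumed proportional to `x`).  A two-stage
#' alternative estimates the SD-vs-x relation from an OLS pre-fit.  Also
#' returns the through-origin fit used for the simplified `Y = A X` model.
#'
#' @param x mean noise bands in uV (> 0).
#' @param y optimal amplitude inclusion thresholds in uV.
#' @param weights `"inverse_x2"` (default), `"two_stage"`, or a numeric
#'   vector of weights.
#' @return object of class `wls_fit`: `slope`, `slope_ci`, `intercept`,
#'   `intercept_ci`, `r2`, `n`, `slope_origin`, `slope_origin_ci`,
#'   `ci_defined`, `weights`.
#' @export
wls_fit <- function(x, y, weights = c("inverse_x2", "two_stage")) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (any(x <= 0)) stop("noise bands must be positive", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate x: all values equal", call. = FALSE)
  if (is.numeric(weights)) {
    w <- weights
    wdesc <- "user-supplied"
  } else {
    weights <- match.arg(weights)
    if (weights == "inverse_x2") {
      w <- 1 / x^2
      wdesc <- "1/x^2 (variance proportional to x^2)"
    } else {
      f0 <- stats::lm(y ~ x)
      sfit <- stats::lm(abs(stats::resid(f0)) ~ x)
      s <- pmax(stats::fitted(sfit), 1e-8)
      w <- 1 / s^2
      wdesc <- "two-stage: 1/fitted(|OLS residual| ~ x)^2"
    }
  }
  # exact data trip stats' "essentially perfect fit" warning; harmless here
  quiet_perfect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  fit <- stats::lm(y ~ x, weights = w)
  n <- length(x)
  ci_defined <- n > 2L
  ci <- if (ci_defined) quiet_perfect(stats::confint(fit)) else
    matrix(NA_real_, 2L, 2L, dimnames = list(c("(Intercept)", "x"), NULL))
  fo <- stats::lm(y ~ 0 + x, weights = w)
  cio <- if (n > 1L && stats::df.residual(fo) > 0) quiet_perfect(stats::confint(fo)) else
    matrix(NA_real_, 1L, 2L)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 slope_ci = unname(ci["x", ]),
                 intercept = unname(stats::coef(fit)[1L]),
                 intercept_ci = unname(ci["(Intercept)", ]),
                 r2 = quiet_perfect(summary(fit)$r.squared), n = n,
                 slope_origin = unname(stats::coef(fo)[1L]),
                 slope_origin_ci = unname(cio[1L, ]),
                 ci_defined = ci_defined, weights = wdesc),
            class = "wls_fit")
}

#' @export
print.wls_fit <- function(x, ...) {
  cat(sprintf("wls_fit (n = %d, weights %s)\n", x$n, x$weights))
  cat(sprintf("  slope %.3g (95%% CI %.3g-%.3g), intercept %.3g (95%% CI %.3g-%.3g), r2 %.3f\n",
              x$slope, x$slope_ci[1L], x$slope_ci[2L], x$intercept,
              x$intercept_ci[1L], x$intercept_ci[2L], x$r2))
  cat(sprintf("  through-origin slope %.3g\n", x$slope_origin))
  invisible(x)
}

#' Lowest inclusion threshold reproducing a manual count
#'
#' Scans a constant amplitude inclusion threshold upward from 0 in
#' `grid_step` increments and returns the lowest value whose FP count
#' (events with peak-trough amplitude strictly above the threshold) falls
#' within one of the manual count.  When no threshold on the grid achieves
#' that, the result is flagged absent (an outlier recording).
#'
#' @param events super-channel event data frame.
#' @param manual_count non-negative integer manual FP count.
#' @param grid_step scan increment in uV (default 1).
#' @return list with `at_inc_uV` (NA when absent), `fp_count` at that
#'   threshold, and logical `absent`.
#' @export
optimal_atinc_search <- function(events, manual_count, grid_step = 1) {
  stopifnot(manual_count >= 0)
  amps <- events$pt_amp_uV
  ths <- seq(0, max(amps, 0) + grid_step, by = grid_step)
  cnt <- vapply(ths, function(t) sum(amps > t), integer(1L))
  ok <- which(abs(cnt - manual_count) <= 1L)
  if (!length(ok)) {
    return(list(at_inc_uV = NA_real_, fp_count = NA_integer_, absent = TRUE))
  }
  list(at_inc_uV = ths[ok[1L]], fp_count = cnt[ok[1L]], absent = FALSE)
}
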