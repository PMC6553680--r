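# End-to-end orchestration: preprocessing -> spike detection -> super-
# channel -> classification -> summary, plus the validation driver.

#' Preprocess a recording and build its super-channel event stream
#'
#' Runs the detection front end: optional perimeter-channel removal,
#' zero-phase bandpass, optional automated bad-channel exclusion, per-
#' channel probability-threshold spike detection, super-channel merging and
#' the QA split.
#'
#' @param rec a [grid_recording].
#' @param bandpass_hz passband `c(low, high)` in Hz.
#' @param inner_grid drop perimeter channels first (default TRUE; skipped
#'   when the grid is too small to have an interior).
#' @param exclude_bad run [detect_bad_channels()] (default TRUE; skipped
#'   when fewer than 4 channels remain).
#' @param spike_p probability for the amplitude threshold.
#' @param qa_max_dur_ms QA split duration bound, see [qa_single_spike()].
#' @return list with `recording` (preprocessed), `spikes`, `events` and
#'   `quality` (NULL when skipped).
#' @export
process_recording <- function(rec, bandpass_hz = c(20, 500), inner_grid = TRUE,
                              exclude_bad = TRUE, spike_p = 0.98,
                              qa_max_dur_ms = 100) {
  stopifnot(inherits(rec, "grid_recording"))
  if (inner_grid && all(rec$grid >= 3L)) rec <- select_inner_grid(rec)
  raw <- rec
  rec <- bandpass(rec, bandpass_hz[1L], bandpass_hz[2L])
  quality <- NULL
  if (exclude_bad && nrow(rec$samples) >= 4L) {
    quality <- detect_bad_channels(rec, raw = raw)
    rec <- apply_channel_exclusion(rec, quality)
  }
  spikes <- detect_channel_spikes(rec, p = spike_p)
  events <- build_superchannel(spikes, rec$fs)
  events <- qa_superchannel(events, rec, max_dur_ms = qa_max_dur_ms)
  list(recording = rec, spikes = spikes, events = events, quality = quality)
}

#' Run the full FP detection pipeline on one recording
#'
#' Composes [process_recording()], [classify_events()],
#' [exclude_noisy_blocks()], [flag_voluntary()] and
#' [summarise_recording()].  When `out_dir` is given, writes the labelled
#' event table, the excluded-block table and the JSON summary, each stamped
#' with the configuration fingerprint.
#'
#' @param input a [grid_recording], or a file path read with
#'   [read_recording()].
#' @param format input format when `input` is a path.
#' @param model a [threshold_model()]; default the noise-responsive linear
#'   model with coefficient 8.
#' @param at_exc amplitude exclusion threshold in uV (default 100; `"off"`
#'   disables block exclusion).
#' @param block_s exclusion block length in seconds.
#' @param max_ifi_ms,min_train voluntary-train rule parameters.
#' @param bandpass_hz,inner_grid,exclude_bad,spike_p,qa_max_dur_ms passed to
#'   [process_recording()].
#' @param out_dir optional output directory.
#' @return list with `summary`, `events`, `blocks`, `quality` and `config`.
#' @export
run_detect <- function(input, format = c("matrix", "edf"),
                       model = threshold_model("linear", 8), at_exc = 100,
                       block_s = 5, max_ifi_ms = 250, min_train = 4,
                       bandpass_hz = c(20, 500), inner_grid = TRUE,
                       exclude_bad = TRUE, spike_p = 0.98,
                       qa_max_dur_ms = 100, out_dir = NULL) {
  rec <- if (inherits(input, "grid_recording")) input else
    read_recording(input, format = match.arg(format))
  config <- list(model_kind = model$kind, coefficient = model$coefficient,
                 at_exc = at_exc, block_s = block_s, max_ifi_ms = max_ifi_ms,
                 min_train = min_train, bandpass_hz = bandpass_hz,
                 inner_grid = inner_grid, exclude_bad = exclude_bad,
                 spike_p = spike_p, qa_max_dur_ms = qa_max_dur_ms)
  hash <- config_hash(config)
  proc <- process_recording(rec, bandpass_hz = bandpass_hz,
                            inner_grid = inner_grid, exclude_bad = exclude_bad,
                            spike_p = spike_p, qa_max_dur_ms = qa_max_dur_ms)
  ev <- classify_events(proc$events, model)
  ex <- exclude_noisy_blocks(ev, rec$duration_s, at_exc = at_exc,
                             block_s = block_s)
  ev <- flag_voluntary(ex$events, max_ifi_ms = max_ifi_ms,
                       min_train = min_train)
  summary <- summarise_recording(ev, rec$duration_s, ex$blocks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_events_tsv(ev, file.path(out_dir, "events.tsv"), hash)
    write_tsv_stamped(ex$blocks, file.path(out_dir, "excluded_blocks.tsv"), hash)
    jsonlite::write_json(
      c(unclass(summary)[c("fp_count", "analysed_time_min", "fp_freq_per_min",
                           "fp_freq_rounded", "n_excluded_blocks")],
        list(model = list(kind = model$kind, coefficient = model$coefficient),
             at_exc_uV = at_exc, config_hash = hash)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  list(summary = summary, events = ev, blocks = ex$blocks,
       quality = proc$quality, config = c(config, config_hash = hash))
}

write_tsv_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_events_tsv <- function(events, path, hash) {
  out <- events
  if (!is.null(out$contributing)) {
    out$contributing <- vapply(out$contributing, function(d) {
      paste(sprintf("%s:%.6g", d$channel_id, d$pt_amp_uV), collapse = ";")
    }, "")
  }
  write_tsv_stamped(out, path, hash)
}

#' Generate a corpus and reduce each recording to its detected events
#'
#' Equivalent to [generate_corpus()] followed by [process_recording()] on
#' every element, but generates and discards one recording at a time so
#' large corpora fit in memory.  The result feeds directly into
#' [roc_curve()], [cross_validate()] and [run_validate()].
#'
#' @inheritParams generate_corpus
#' @param ... passed to [process_recording()].
#' @return list of `list(events, peaks, truth)` elements.
#' @export
detect_corpus_events <- function(base_cfg, n_recordings, heterogeneity = 0.5,
                                 annotation_miss_rate = 0,
                                 annotation_false_rate = 0, seed = 1, ...) {
  stopifnot(inherits(base_cfg, "sim_config"), n_recordings >= 2L)
  set.seed(seed)
  factors <- exp(stats::rnorm(n_recordings, 0, heterogeneity))
  rec_seeds <- sample.int(2^30, n_recordings)
  lapply(seq_len(n_recordings), function(i) {
    el <- corpus_element(base_cfg, factors[i], rec_seeds[i], i,
                         annotation_miss_rate, annotation_false_rate)
    proc <- process_recording(el$recording, ...)
    list(events = proc$events, peaks = el$annotation$peak_times_s,
         truth = el$truth)
  })
}

#' Run the validation machinery over an annotated corpus
#'
#' Each corpus recording is reduced to its super-channel events (block and
#' voluntary exclusions stay disabled, as required for event matching),
#' then median ROC curves are computed for both threshold-model families,
#' the optimal coefficients selected, and repeated k-fold cross-validation
#' run on the linear model.
#'
#' @param corpus list of `list(recording, annotation)` elements (the
#'   `truth` element of [generate_corpus()] output is ignored if present);
#'   alternatively pre-detected `list(events, peaks)` elements.
#' @param thresholds_linear,thresholds_constant threshold grids (defaults:
#'   the standard A2 / A1 grids).
#' @param k,repeats,seed cross-validation controls.
#' @param out_dir optional output directory for ROC/CV tables.
#' @param ... passed to [process_recording()].
#' @return list with `roc_linear`, `roc_constant`, `optimal_a2`,
#'   `optimal_a1`, `cv` and `config`.
#' @export
run_validate <- function(corpus, thresholds_linear = NULL,
                         thresholds_constant = NULL, k = 5, repeats = 100,
                         seed = 1, out_dir = NULL, ...) {
  vc <- lapply(corpus, function(el) {
    if (!is.null(el$events)) {
      list(events = el$events, peaks = el$peaks)
    } else {
      proc <- process_recording(el$recording, ...)
      list(events = proc$events, peaks = el$annotation$peak_times_s)
    }
  })
  if (length(vc) < k) stop("cross-validation needs at least k recordings", call. = FALSE)
  roc_lin <- roc_curve(vc, "linear", thresholds_linear)
  roc_con <- roc_curve(vc, "constant", thresholds_constant)
  cv <- cross_validate(vc, candidate_a2 = roc_lin$thresholds, k = k,
                       repeats = repeats, seed = seed)
  config <- list(k = k, repeats = repeats, seed = seed,
                 thresholds_linear = roc_lin$thresholds,
                 thresholds_constant = roc_con$thresholds)
  hash <- config_hash(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_stamped(roc_lin$table, file.path(out_dir, "roc_linear.tsv"), hash)
    write_tsv_stamped(roc_con$table, file.path(out_dir, "roc_constant.tsv"), hash)
    write_tsv_stamped(cv$by_a2, file.path(out_dir, "cv_by_a2.tsv"), hash)
    jsonlite::write_json(
      list(auc_linear_pct = roc_lin$auc_pct, auc_constant_pct = roc_con$auc_pct,
           optimal_a2 = optimal_threshold(roc_lin),
           optimal_a1 = optimal_threshold(roc_con),
           cv_modal_a2 = cv$modal_a2, cv_modal_fraction = cv$modal_fraction,
           config_hash = hash),
      file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA)
  }
  list(roc_linear = roc_lin, roc_constant = roc_con,
       optimal_a2 = optimal_threshold(roc_lin),
       optimal_a1 = optimal_threshold(roc_con), cv = cv,
       config = c(config, config_hash = hash))
}
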