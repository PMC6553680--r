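# Classification of super-channel events as fasciculation potentials (FPs)
# using an amplitude inclusion threshold, exclusion of noisy 5-second
# blocks via the amplitude exclusion threshold, voluntary-train filtering,
# and per-recording frequency summaries.

#' Amplitude-inclusion threshold model
#'
#' Two families of amplitude inclusion threshold (the minimum peak-trough
#' amplitude for an event to count as an FP):
#' * `"constant"`: the threshold ignores noise, `Y = A1` (uV);
#' * `"linear"` (noise-responsive): the threshold scales with the event's
#'   local noise band `X`, `Y = A2 * X`; `A2 = 8` is the validated optimum.
#'
#' @param kind `"linear"` or `"constant"`.
#' @param coefficient positive number: `A2` (dimensionless) for the linear
#'   model, `A1` (uV) for the constant model.
#' @return object of class `threshold_model`.
#' @export
threshold_model <- function(kind = c("linear", "constant"), coefficient = 8) {
  kind <- match.arg(kind)
  stop_if_not_scalar_pos(coefficient, "coefficient")
  structure(list(kind = kind, coefficient = coefficient),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  if (x$kind == "linear") {
    cat(sprintf("threshold_model: Y = %g * X (noise-responsive)\n", x$coefficient))
  } else {
    cat(sprintf("threshold_model: Y = %g uV (constant)\n", x$coefficient))
  }
  invisible(x)
}

#' Amplitude inclusion threshold for a noise band
#'
#' @param model a [threshold_model()].
#' @param noise_band_uV noise band(s) `X` in uV (>= 0); vectorised.
#' @return threshold(s) `Y` in uV.
#' @export
at_inc <- function(model, noise_band_uV) {
  stopifnot(inherits(model, "threshold_model"))
  if (any(noise_band_uV < 0)) stop("negative noise band", call. = FALSE)
  if (model$kind == "constant") {
    rep(model$coefficient, length(noise_band_uV))
  } else {
    model$coefficient * noise_band_uV
  }
}

#' Classify super-channel events against the inclusion threshold
#'
#' Each event is labelled `"fp"` when its peak-trough amplitude strictly
#' exceeds its amplitude inclusion threshold (computed from the event's own
#' noise band), else `"subthreshold"`.  The per-event threshold is stored
#' in `at_inc_uV`.
#'
#' @param events event data frame (see [build_superchannel()]).
#' @param model a [threshold_model()].
#' @return the events with `at_inc_uV` and `label` columns added.
#' @export
classify_events <- function(events, model) {
  events$at_inc_uV <- if (nrow(events)) at_inc(model, events$noise_band_uV) else numeric()
  events$label <- if (nrow(events)) {
    ifelse(events$pt_amp_uV > events$at_inc_uV, "fp", "subthreshold")
  } else {
    character()
  }
  events
}

#' Exclude uninterpretably noisy five-second blocks
#'
#' The recording is tiled into consecutive blocks of `block_s` seconds from
#' t = 0 (the final block may be shorter).  A block is excluded when either
#' (a) the per-spike inclusion threshold exceeds `at_exc` for strictly more
#' than half of the spikes in the block, or (b) at least one spike's
#' inclusion threshold exceeds twice `at_exc`.  All events whose peak falls
#' in an excluded block are relabelled `"excluded_block"`, and the excluded
#' time is later subtracted from the frequency denominator.  Empty blocks
#' are never excluded.
#'
#' @param events classified event data frame (see [classify_events()]).
#' @param duration_s total recording duration in seconds.
#' @param at_exc amplitude exclusion threshold in uV (default 100); `"off"`,
#'   `NULL` or a non-finite value disables block exclusion.
#' @param block_s block duration in seconds (default 5).
#' @return list with `events` (relabelled) and `blocks`, a data frame of the
#'   excluded blocks (`start_s`, `end_s`, `reason`, `n_spikes`).
#' @export
exclude_noisy_blocks <- function(events, duration_s, at_exc = 100, block_s = 5) {
  no_blocks <- data.frame(start_s = numeric(), end_s = numeric(),
                          reason = character(), n_spikes = integer())
  if (is.null(at_exc) || (is.character(at_exc) && identical(at_exc, "off")) ||
      !is.finite(at_exc)) {
    return(list(events = events, blocks = no_blocks))
  }
  stop_if_not_scalar_pos(at_exc, "at_exc")
  if (!nrow(events)) return(list(events = events, blocks = no_blocks))
  stopifnot(all(events$peak_s >= 0), all(events$peak_s <= duration_s))
  blk <- pmin(floor(events$peak_s / block_s),
              ceiling(duration_s / block_s) - 1)
  excl <- list()
  for (b in sort(unique(blk))) {
    y <- events$at_inc_uV[blk == b]
    over2 <- any(y > 2 * at_exc)
    majority <- sum(y > at_exc) > length(y) / 2
    reason <- if (over2) {
      "single_over_2x_atexc"
    } else if (majority) {
      "majority_over_atexc"
    } else {
      next
    }
    excl[[length(excl) + 1L]] <- data.frame(
      start_s = b * block_s, end_s = min((b + 1) * block_s, duration_s),
      reason = reason, n_spikes = length(y), stringsAsFactors = FALSE)
    events$label[blk == b] <- "excluded_block"
  }
  blocks <- if (length(excl)) do.call(rbind, excl) else no_blocks
  list(events = events, blocks = blocks)
}

#' Flag voluntary-activity trains
#'
#' A train of at least `min_train` consecutive FP-labelled events in which
#' every peak-to-peak inter-FP interval is below `max_ifi_ms` represents
#' regular voluntary motor-unit firing rather than fasciculation; the whole
#' run is relabelled `"voluntary"`.
#'
#' @param events classified event data frame, time-sorted.
#' @param max_ifi_ms maximal inter-FP interval within a train (default 250).
#' @param min_train minimal run length (default 4).
#' @return the events with voluntary trains relabelled.
#' @export
flag_voluntary <- function(events, max_ifi_ms = 250, min_train = 4) {
  idx <- which(events$label == "fp")
  if (length(idx) < min_train) return(events)
  short <- diff(events$peak_s[idx]) < max_ifi_ms / 1000
  r <- rle(short)
  pos <- cumsum(c(1L, r$lengths))
  for (j in which(r$values & r$lengths >= min_train - 1L)) {
    run <- idx[pos[j]:(pos[j] + r$lengths[j])]   # L gaps cover L + 1 events
    events$label[run] <- "voluntary"
  }
  events
}

#' Per-recording FP summary
#'
#' Counts FP-labelled events, subtracts excluded-block time from the
#' denominator, and reports the FP frequency per minute of analysed time.
#' The frequency is kept at full precision internally; `fp_freq_rounded`
#' applies the round-half-up integer display convention.  Inter-FP
#' intervals are computed between consecutive FP peaks; intervals spanning
#' an excluded block are flagged.
#'
#' @param events labelled event data frame.
#' @param duration_s total recording duration in seconds.
#' @param blocks excluded-block data frame from [exclude_noisy_blocks()].
#' @return object of class `recording_summary`: `fp_count`,
#'   `analysed_time_min`, `fp_freq_per_min`, `fp_freq_rounded`, `ifi_s`,
#'   `ifi_spans_exclusion`, `n_excluded_blocks`.
#' @export
summarise_recording <- function(events, duration_s,
                                blocks = data.frame(start_s = numeric(),
                                                    end_s = numeric())) {
  fp <- events[events$label == "fp", , drop = FALSE]
  excl_s <- sum(blocks$end_s - blocks$start_s)
  analysed_min <- (duration_s - excl_s) / 60
  if (analysed_min <= 0) stop("no analysable time; frequency undefined", call. = FALSE)
  freq <- nrow(fp) / analysed_min
  pk <- sort(fp$peak_s)
  ifi <- diff(pk)
  spans <- if (length(ifi)) {
    vapply(seq_along(ifi), function(i) {
      any(blocks$start_s >= pk[i] & blocks$start_s < pk[i + 1L])
    }, logical(1L))
  } else {
    logical(0)
  }
  structure(list(fp_count = nrow(fp),
                 analysed_time_min = analysed_min,
                 fp_freq_per_min = freq,
                 fp_freq_rounded = round_half_up(freq),
                 ifi_s = ifi, ifi_spans_exclusion = spans,
                 n_excluded_blocks = nrow(blocks)),
            class = "recording_summary")
}

#' @export
print.recording_summary <- function(x, ...) {
  cat(sprintf("recording_summary: %d FPs, %.3f min analysed, %d/min (%d block(s) excluded)\n",
              x$fp_count, x$analysed_time_min, x$fp_freq_rounded,
              x$n_excluded_blocks))
  invisible(x)
}
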