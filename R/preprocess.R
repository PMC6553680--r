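#' Zero-phase bandpass filter
#'
#' Applies a 4th-order Butterworth bandpass (default 20-500 Hz, no notch)
#' forward and backward over each channel, so spike peaks are not shifted
#' in time.
#'
#' @param rec a [grid_recording].
#' @param low,high passband edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @return the filtered [grid_recording] (duration preserved).
#' @export
bandpass <- function(rec, low = 20, high = 500) {
  stopifnot(inherits(rec, "grid_recording"))
  fs <- rec$fs
  if (!(low > 0 && low < high)) stop("need 0 < low < high", call. = FALSE)
  if (high >= fs / 2) stop("upper edge must be below the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  for (ch in seq_len(nrow(rec$samples))) {
    rec$samples[ch, ] <- signal::filtfilt(bf, rec$samples[ch, ])
  }
  rec$meta$bandpass_hz <- c(low, high)
  rec
}

#' Drop perimeter channels of the electrode grid
#'
#' The outermost electrodes of a surface grid have the poorest skin contact;
#' this keeps only channels strictly inside the grid border (an 8x8 grid
#' keeps its 36 interior channels).  Positions are re-indexed to the reduced
#' grid; channel labels are retained.
#'
#' @param rec a [grid_recording].
#' @return a [grid_recording] on the `(rows-2) x (cols-2)` interior grid;
#'   may hold zero channels.
#' @export
select_inner_grid <- function(rec) {
  stopifnot(inherits(rec, "grid_recording"))
  rows <- rec$grid[1L]; cols <- rec$grid[2L]
  keep <- rec$positions[, 1L] > 1L & rec$positions[, 1L] < rows &
    rec$positions[, 2L] > 1L & rec$positions[, 2L] < cols
  grid_recording(rec$samples[keep, , drop = FALSE], fs = rec$fs,
                 grid = pmax(c(rows - 2L, cols - 2L), 0L),
                 channel_ids = rec$channel_ids[keep],
                 positions = rec$positions[keep, , drop = FALSE] - 1L,
                 meta = rec$meta)
}

#' Automated bad-channel detection
#'
#' Flags null channels (amplitude range below a floor), then computes three
#' per-channel quality metrics -- total FFT-magnitude area in the passband,
#' amplitude range, and the fraction of spectral power below the passband
#' (baseline drift) -- and excludes channels falling outside the 95%
#' confidence interval (mean +/- 1.96 SD across non-null channels) on any
#' metric.  The drift metric is taken from the pre-filter signal when `raw`
#' is supplied, since drift is largely removed by the bandpass.
#'
#' @param rec a (typically bandpassed) [grid_recording].
#' @param raw optional unfiltered [grid_recording] with the same channels,
#'   used for the drift metric.
#' @param null_floor_uV amplitude-range floor below which a channel is
#'   declared null (absent electrical contact).
#' @param ci_z z-multiplier for the confidence interval (1.96 = 95%).
#' @param band passband in Hz delimiting the spectral metrics.
#' @return a data frame of class `channel_quality_report` with one row per
#'   channel: metrics, `excluded` flag and a single primary `reason`
#'   (`"null"`, `"noisy"`, `"drift"` or `"out_of_CI"`); attribute
#'   `n_surviving` gives the surviving channel count.
#' @export
detect_bad_channels <- function(rec, raw = NULL, null_floor_uV = 0.5,
                                ci_z = 1.96, band = c(20, 500)) {
  stopifnot(inherits(rec, "grid_recording"))
  n_ch <- nrow(rec$samples)
  if (n_ch < 4L) stop("need at least 4 channels to estimate the CI", call. = FALSE)
  if (!is.null(raw)) stopifnot(nrow(raw$samples) == n_ch)
  n <- ncol(rec$samples)
  freqs <- (seq_len(n) - 1L) / n * rec$fs
  half <- freqs <= rec$fs / 2
  in_band <- half & freqs >= band[1L] & freqs <= band[2L]
  below <- half & freqs < band[1L]
  amp_range <- apply(rec$samples, 1L, function(x) max(x) - min(x))
  spectral_auc <- numeric(n_ch)
  drift_fraction <- numeric(n_ch)
  drift_src <- if (is.null(raw)) rec$samples else raw$samples
  for (ch in seq_len(n_ch)) {
    spectral_auc[ch] <- sum(Mod(stats::fft(rec$samples[ch, ]))[in_band]) / n
    pw <- Mod(stats::fft(drift_src[ch, ]))[half]^2
    drift_fraction[ch] <- if (sum(pw) > 0) sum(pw[below[half]]) / sum(pw) else 0
  }
  is_null <- amp_range < null_floor_uV
  excluded <- is_null
  reason <- rep(NA_character_, n_ch)
  reason[is_null] <- "null"
  degenerate <- sum(!is_null) < 4L
  if (degenerate) {
    warning("fewer than 4 non-null channels; CI-based exclusion skipped")
  } else {
    metrics <- list(spectral_auc = spectral_auc, amp_range = amp_range,
                    drift_fraction = drift_fraction)
    hi <- lo <- list()
    for (m in names(metrics)) {
      v <- metrics[[m]][!is_null]
      hi[[m]] <- mean(v) + ci_z * stats::sd(v)
      lo[[m]] <- mean(v) - ci_z * stats::sd(v)
    }
    for (ch in which(!is_null)) {
      noisy <- amp_range[ch] > hi$amp_range || spectral_auc[ch] > hi$spectral_auc
      drifty <- drift_fraction[ch] > hi$drift_fraction
      low_ci <- amp_range[ch] < lo$amp_range || spectral_auc[ch] < lo$spectral_auc ||
        drift_fraction[ch] < lo$drift_fraction
      if (noisy || drifty || low_ci) {
        excluded[ch] <- TRUE
        reason[ch] <- if (noisy) "noisy" else if (drifty) "drift" else "out_of_CI"
      }
    }
  }
  out <- data.frame(channel_id = rec$channel_ids, spectral_auc = spectral_auc,
                    amp_range = amp_range, drift_fraction = drift_fraction,
                    excluded = excluded, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("channel_quality_report", "data.frame")
  attr(out, "n_surviving") <- sum(!excluded)
  attr(out, "ci_skipped") <- degenerate
  out
}

#' Subset a recording to the channels a quality report kept
#'
#' @param rec a [grid_recording].
#' @param report a `channel_quality_report` from [detect_bad_channels()].
#' @return the [grid_recording] restricted to non-excluded channels.
#' @export
apply_channel_exclusion <- function(rec, report) {
  stopifnot(inherits(rec, "grid_recording"),
            inherits(report, "channel_quality_report"),
            nrow(report) == nrow(rec$samples))
  keep <- !report$excluded
  grid_recording(rec$samples[keep, , drop = FALSE], fs = rec$fs,
                 grid = rec$grid, channel_ids = rec$channel_ids[keep],
                 positions = rec$positions[keep, , drop = FALSE],
                 meta = rec$meta)
}
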