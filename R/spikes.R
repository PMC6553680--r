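# Spike detection: empirical amplitude-probability threshold, zero-crossing
# segmentation with opposite-polarity phase joining, and local noise bands.
#
# Sample-index convention throughout: 1-based, half-open [onset_i, offset_i),
# i.e. the spike occupies samples onset_i .. offset_i - 1.

#' Empirical amplitude-probability threshold
#'
#' Returns the amplitude `t` such that the empirical fraction of samples
#' with `|amplitude| <= t` equals `p`: the p-quantile (inverse ECDF) of the
#' absolute amplitude distribution of the channel.  Samples beyond `t`
#' (the top `1 - p` of the distribution) become spike candidates.
#'
#' @param signal numeric vector of channel samples (uV).
#' @param p probability in (0, 1); default 0.98.
#' @return threshold in uV (>= 0).
#' @export
probability_threshold <- function(signal, p = 0.98) {
  stopifnot(length(signal) > 0L, p > 0, p < 1)
  if (all(signal == 0)) {
    warning("degenerate all-zero signal; threshold is 0")
    return(0)
  }
  stats::quantile(abs(signal), probs = p, type = 1L, names = FALSE)
}

#' Segment suprathreshold spikes by zero crossings
#'
#' The signal is partitioned into phases: maximal runs of constant nonzero
#' sign, delimited by zero crossings (a sign change between consecutive
#' samples; exact zeros count as crossings and belong to no phase).  A phase
#' is suprathreshold when its absolute maximum exceeds `threshold`.
#' Immediately adjacent suprathreshold phases -- sharing a zero crossing and
#' therefore of opposite polarity -- are joined transitively into a single
#' spike, so a biphasic or triphasic excursion is reported once.  Each
#' spike's onset/offset are the zero crossings (or signal edges) bounding
#' its phase chain.
#'
#' @param signal numeric vector of channel samples (uV).
#' @param threshold amplitude threshold in uV (>= 0).
#' @return data frame with one row per spike: `onset_i`, `offset_i`
#'   (half-open), `peak_i` (sample of max |amplitude|), `peak_uV`,
#'   `trough_uV`, `pt_amp_uV` (peak minus trough).  Sorted by onset,
#'   non-overlapping.
#' @export
segment_spikes <- function(signal, threshold) {
  stopifnot(is.numeric(signal), threshold >= 0)
  empty <- data.frame(onset_i = integer(), offset_i = integer(),
                      peak_i = integer(), peak_uV = numeric(),
                      trough_uV = numeric(), pt_amp_uV = numeric())
  if (!length(signal)) return(empty)
  r <- rle(as.integer(sign(signal)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nz <- which(r$values != 0L)
  if (!length(nz)) return(empty)
  supra <- vapply(nz, function(j) {
    max(abs(signal[starts[j]:ends[j]])) > threshold
  }, logical(1L))
  keep <- nz[supra]
  if (!length(keep)) return(empty)
  # consecutive rle entries are adjacent phases (opposite polarity by
  # construction); a zero-run or subthreshold phase in between breaks the chain
  grp <- cumsum(c(1L, diff(keep) != 1L))
  onset <- tapply(starts[keep], grp, min)
  offend <- tapply(ends[keep], grp, max)
  out <- data.frame(onset_i = as.integer(onset), offset_i = as.integer(offend) + 1L)
  out$peak_i <- NA_integer_
  out$peak_uV <- out$trough_uV <- NA_real_
  for (i in seq_len(nrow(out))) {
    idx <- out$onset_i[i]:(out$offset_i[i] - 1L)
    seg <- signal[idx]
    out$peak_i[i] <- idx[which.max(abs(seg))]
    out$peak_uV[i] <- max(seg)
    out$trough_uV[i] <- min(seg)
  }
  out$pt_amp_uV <- out$peak_uV - out$trough_uV
  out
}

#' Local noise band around a spike
#'
#' The noise band is the difference between the mean positive amplitude and
#' the mean negative amplitude over one second either side of the spike
#' (window `[onset - halfwidth, offset + halfwidth)`, excluding the spike's
#' own samples, truncated at the signal edges).  A missing polarity
#' contributes 0, so the band is always non-negative for a zero-mean
#' context.  Defined this way the noise estimate is directly comparable
#' with spike peak-trough amplitudes.
#'
#' @param signal numeric vector of channel samples (uV).
#' @param onset_i,offset_i spike boundaries (1-based, half-open).
#' @param fs sampling rate in Hz.
#' @param halfwidth_s context half-width in seconds (default 1).
#' @return noise band in uV (>= 0 for zero-mean noise).
#' @export
noise_band <- function(signal, onset_i, offset_i, fs, halfwidth_s = 1) {
  stopifnot(onset_i >= 1L, offset_i > onset_i, offset_i <= length(signal) + 1L)
  spikes <- data.frame(onset_i = onset_i, offset_i = offset_i)
  noise_band_all(signal, spikes, fs, halfwidth_s)[1L]
}

# vectorised noise bands via cumulative sums; O(1) per spike
noise_band_all <- function(signal, spikes, fs, halfwidth_s = 1) {
  n <- length(signal)
  hw <- as.integer(round(halfwidth_s * fs))
  cp <- cumsum(pmax(signal, 0)); np <- cumsum(signal > 0)
  cm <- cumsum(pmin(signal, 0)); nm <- cumsum(signal < 0)
  rsum <- function(cs, a, b) {
    if (b < a) return(0)
    cs[b] - if (a > 1L) cs[a - 1L] else 0
  }
  out <- numeric(nrow(spikes))
  for (i in seq_len(nrow(spikes))) {
    on <- spikes$onset_i[i]; off <- spikes$offset_i[i]
    l1 <- max(1L, on - hw); l2 <- on - 1L          # left context
    r1 <- off; r2 <- min(n, off - 1L + hw)          # right context
    pos_s <- rsum(cp, l1, l2) + rsum(cp, r1, r2)
    pos_n <- rsum(np, l1, l2) + rsum(np, r1, r2)
    neg_s <- rsum(cm, l1, l2) + rsum(cm, r1, r2)
    neg_n <- rsum(nm, l1, l2) + rsum(nm, r1, r2)
    n_ctx <- max(0L, l2 - l1 + 1L) + max(0L, r2 - r1 + 1L)
    if (n_ctx == 0L) {
      warning("spike spans the whole signal; noise band is 0")
      out[i] <- 0
      next
    }
    mp <- if (pos_n > 0) pos_s / pos_n else 0
    mn <- if (neg_n > 0) neg_s / neg_n else 0
    out[i] <- mp - mn
  }
  out
}

#' Detect spikes on every channel of a recording
#'
#' Per channel: computes the [probability_threshold()], segments spikes with
#' [segment_spikes()], and attaches each spike's local [noise_band()].
#'
#' @param rec a preprocessed [grid_recording].
#' @param p probability for the amplitude threshold (default 0.98).
#' @param halfwidth_s noise-band context half-width in seconds.
#' @return data frame of spikes across channels with columns `channel_id`,
#'   `channel_idx` (position in the recording's channel order, used for
#'   deterministic tie-breaking downstream), the [segment_spikes()] columns
#'   and `noise_band_uV`; attribute `fs` carries the sampling rate.
#' @export
detect_channel_spikes <- function(rec, p = 0.98, halfwidth_s = 1) {
  stopifnot(inherits(rec, "grid_recording"))
  parts <- vector("list", nrow(rec$samples))
  for (ch in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ch, ]
    if (all(x == 0)) next
    th <- probability_threshold(x, p = p)
    sp <- segment_spikes(x, th)
    if (!nrow(sp)) next
    sp$noise_band_uV <- noise_band_all(x, sp, rec$fs, halfwidth_s)
    sp$channel_id <- rec$channel_ids[ch]
    sp$channel_idx <- ch
    parts[[ch]] <- sp
  }
  parts <- parts[!vapply(parts, is.null, logical(1L))]
  out <- if (length(parts)) do.call(rbind, parts) else
    data.frame(onset_i = integer(), offset_i = integer(), peak_i = integer(),
               peak_uV = numeric(), trough_uV = numeric(), pt_amp_uV = numeric(),
               noise_band_uV = numeric(), channel_id = character(),
               channel_idx = integer())
  rownames(out) <- NULL
  attr(out, "fs") <- rec$fs
  out
}
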