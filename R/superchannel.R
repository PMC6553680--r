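# Super-channel construction: temporally coincident spikes across channels
# collapse to a single event stream; each event keeps the channel of origin
# with the maximal peak-trough amplitude.

empty_events <- function() {
  data.frame(onset_s = numeric(), offset_s = numeric(), peak_s = numeric(),
             onset_i = integer(), offset_i = integer(), peak_i = integer(),
             origin_channel = character(), origin_channel_idx = integer(),
             pt_amp_uV = numeric(), noise_band_uV = numeric(),
             n_channels = integer(), contributing = I(list()))
}

#' Merge per-channel spikes into a super-channel event stream
#'
#' Spikes whose `[onset, offset)` intervals overlap across channels (at
#' least one shared sample) are grouped by transitive closure into one
#' event.  The event adopts the interval, peak time, peak-trough amplitude
#' and noise band of the contributing spike with the maximal peak-trough
#' amplitude (ties broken by lower channel index, then earlier onset), and
#' records every contributing spike.
#'
#' @param spikes data frame from [detect_channel_spikes()] (any channel
#'   order); must carry `channel_idx` and sample-index columns.
#' @param fs sampling rate in Hz (defaults to the `fs` attribute of
#'   `spikes`).
#' @return data frame of events sorted by onset and disjoint in time, with
#'   columns `onset_s`, `offset_s`, `peak_s`, the origin-channel sample
#'   indices, `origin_channel`, `pt_amp_uV`, `noise_band_uV`, `n_channels`
#'   (distinct contributing channels) and a `contributing` list-column of
#'   per-spike (`channel_id`, `pt_amp_uV`) tables.
#' @export
build_superchannel <- function(spikes, fs = attr(spikes, "fs")) {
  if (is.null(fs)) stop("sampling rate 'fs' required", call. = FALSE)
  if (!nrow(spikes)) return(empty_events())
  sp <- spikes[order(spikes$onset_i, spikes$channel_idx), , drop = FALSE]
  n <- nrow(sp)
  grp <- integer(n)
  grp[1L] <- 1L
  max_off <- sp$offset_i[1L]
  for (i in seq_len(n)[-1L]) {
    if (sp$onset_i[i] < max_off) {        # half-open intervals share a sample
      grp[i] <- grp[i - 1L]
    } else {
      grp[i] <- grp[i - 1L] + 1L
    }
    max_off <- max(max_off, sp$offset_i[i])
  }
  # per-group lead spike (max pt_amp; ties: lower channel index, earlier
  # onset) picked without per-group data-frame construction, which would
  # dominate runtime on dense noise-event streams
  ord2 <- order(grp, -sp$pt_amp_uV, sp$channel_idx, sp$onset_i)
  lead_rows <- ord2[!duplicated(grp[ord2])]
  lead <- sp[lead_rows, , drop = FALSE]
  ch_split <- split(sp$channel_id, grp)
  amp_split <- split(sp$pt_amp_uV, grp)
  contributing <- mapply(function(ch, amp) {
    structure(list(channel_id = ch, pt_amp_uV = amp),
              class = "data.frame", row.names = seq_along(ch))
  }, ch_split, amp_split, SIMPLIFY = FALSE)
  names(contributing) <- NULL
  out <- data.frame(onset_s = (lead$onset_i - 1L) / fs,
                    offset_s = (lead$offset_i - 1L) / fs,
                    peak_s = (lead$peak_i - 1L) / fs,
                    onset_i = lead$onset_i, offset_i = lead$offset_i,
                    peak_i = lead$peak_i,
                    origin_channel = lead$channel_id,
                    origin_channel_idx = lead$channel_idx,
                    pt_amp_uV = lead$pt_amp_uV,
                    noise_band_uV = lead$noise_band_uV,
                    n_channels = vapply(ch_split, function(z)
                      length(unique(z)), integer(1L), USE.NAMES = FALSE),
                    stringsAsFactors = FALSE)
  out$contributing <- contributing
  rownames(out) <- NULL
  attr(out, "fs") <- fs
  out
}

#' Quality-assurance split of compound events
#'
#' Heuristic safeguard that each reported event represents a single spike:
#' when an event is longer than `max_dur_ms` *and* its origin-channel
#' segment contains two or more local absolute-amplitude maxima above the
#' event's noise band that are separated by a return to within the noise
#' band, the event is split at the minimal-|amplitude| sample between the
#' maxima.  Duration alone never splits an event.  The split rule and its
#' parameters are a heuristic of this package; per-piece peak, trough and
#' peak-trough amplitude are recomputed, while the origin channel and noise
#' band are inherited.
#'
#' @param event single-row event data frame (see [build_superchannel()]).
#' @param signal samples of the event's origin channel (uV).
#' @param fs sampling rate in Hz.
#' @param max_dur_ms events at or below this duration are never split.
#' @return data frame of one or more events.
#' @export
qa_single_spike <- function(event, signal, fs, max_dur_ms = 100) {
  stopifnot(nrow(event) == 1L)
  dur_ms <- (event$offset_i - event$onset_i) / fs * 1000
  if (dur_ms <= max_dur_ms) return(event)
  idx <- event$onset_i:(event$offset_i - 1L)
  a <- abs(signal[idx])
  nb <- event$noise_band_uV
  d <- diff(sign(diff(a)))
  loc <- which(d < 0) + 1L
  loc <- loc[a[loc] > nb]
  if (length(loc) < 2L) return(event)
  cuts <- integer(0)
  for (j in seq_len(length(loc) - 1L)) {
    between <- (loc[j] + 1L):(loc[j + 1L] - 1L)
    if (!length(between)) next
    if (min(a[between]) <= nb) {
      cuts <- c(cuts, between[which.min(a[between])])
    }
  }
  if (!length(cuts)) return(event)
  bounds <- c(1L, cuts, length(idx) + 1L)
  pieces <- lapply(seq_len(length(bounds) - 1L), function(k) {
    rel <- bounds[k]:(bounds[k + 1L] - 1L)
    seg_idx <- idx[rel]
    seg <- signal[seg_idx]
    piece <- event
    piece$onset_i <- seg_idx[1L]
    piece$offset_i <- seg_idx[length(seg_idx)] + 1L
    piece$peak_i <- seg_idx[which.max(abs(seg))]
    piece$onset_s <- (piece$onset_i - 1L) / fs
    piece$offset_s <- (piece$offset_i - 1L) / fs
    piece$peak_s <- (piece$peak_i - 1L) / fs
    piece$pt_amp_uV <- max(seg) - min(seg)
    piece
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Apply the QA split across a super-channel stream
#'
#' @param events event data frame from [build_superchannel()].
#' @param rec the [grid_recording] the events came from (provides the
#'   origin-channel signals).
#' @param max_dur_ms see [qa_single_spike()].
#' @return the QA-processed event stream, still sorted and disjoint.
#' @export
qa_superchannel <- function(events, rec, max_dur_ms = 100) {
  stopifnot(inherits(rec, "grid_recording"))
  if (!nrow(events)) return(events)
  dur_ms <- (events$offset_i - events$onset_i) / rec$fs * 1000
  long <- which(dur_ms > max_dur_ms)
  if (!length(long)) {
    attr(events, "fs") <- rec$fs
    return(events)
  }
  # only over-long events can split; splice their pieces back in order
  chunks <- list()
  last <- 0L
  for (i in long) {
    if (i > last + 1L) chunks[[length(chunks) + 1L]] <- events[(last + 1L):(i - 1L), ]
    ev <- events[i, , drop = FALSE]
    chunks[[length(chunks) + 1L]] <-
      qa_single_spike(ev, rec$samples[ev$origin_channel_idx, ], rec$fs,
                      max_dur_ms = max_dur_ms)
    last <- i
  }
  if (last < nrow(events)) chunks[[length(chunks) + 1L]] <- events[(last + 1L):nrow(events), ]
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  attr(out, "fs") <- rec$fs
  out
}
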