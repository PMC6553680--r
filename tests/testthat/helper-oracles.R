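# Independent brute-force oracles, implemented as direct per-sample /
# per-pair scans so they share no code path with the package internals.

# spike segmentation by a literal walk over samples: label phases (maximal
# runs of constant nonzero sign), mark suprathreshold phases, chain phases
# that touch without a zero-sample gap
brute_segment_spikes <- function(x, threshold) {
  n <- length(x)
  phase <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (x[i] == 0) next
    if (i == 1L || x[i - 1L] == 0 || sign(x[i]) != sign(x[i - 1L])) cur <- cur + 1L
    phase[i] <- cur
  }
  if (cur == 0L) {
    return(data.frame(onset_i = integer(), offset_i = integer(),
                      peak_i = integer(), pt_amp_uV = numeric()))
  }
  starts <- vapply(seq_len(cur), function(p) min(which(phase == p)), integer(1))
  ends <- vapply(seq_len(cur), function(p) max(which(phase == p)), integer(1))
  supra <- vapply(seq_len(cur), function(p) {
    max(abs(x[starts[p]:ends[p]])) > threshold
  }, logical(1))
  spikes <- list()
  p <- 1L
  while (p <= cur) {
    if (!supra[p]) { p <- p + 1L; next }
    q <- p
    while (q < cur && supra[q + 1L] && starts[q + 1L] == ends[q] + 1L) q <- q + 1L
    idx <- starts[p]:ends[q]
    spikes[[length(spikes) + 1L]] <- data.frame(
      onset_i = starts[p], offset_i = ends[q] + 1L,
      peak_i = idx[which.max(abs(x[idx]))],
      pt_amp_uV = max(x[idx]) - min(x[idx]))
    p <- q + 1L
  }
  do.call(rbind, spikes)
}

# connected components of the interval-overlap graph by repeated pairwise
# merging (O(n^3), fine for oracle sizes)
brute_overlap_components <- function(onset, offset) {
  n <- length(onset)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] && onset[i] < offset[j] && onset[j] < offset[i]) {
          m <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

# confusion counts by direct accounting over disjoint events: an included
# event with at least one annotated peak inside is a true positive (peaks
# in at most one event, so one-to-one matching is trivially maximal)
brute_confusion <- function(peaks, events) {
  inside <- function(ev) sum(peaks >= ev[["onset_s"]] & peaks < ev[["offset_s"]])
  n_in <- vapply(seq_len(nrow(events)), function(i) inside(events[i, ]), numeric(1))
  included <- events$label == "fp"
  tp <- sum(included & n_in > 0)
  list(tp = tp,
       fp = sum(included & n_in == 0),
       fn = length(peaks) - tp,
       tn = sum(!included & n_in == 0))
}

# minimal event table for classification/validation tests
make_event_table <- function(peak_s, pt_amp_uV, noise_band_uV,
                             width_s = 0.01) {
  data.frame(onset_s = peak_s - width_s / 2, offset_s = peak_s + width_s / 2,
             peak_s = peak_s, pt_amp_uV = pt_amp_uV,
             noise_band_uV = noise_band_uV, stringsAsFactors = FALSE)
}
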