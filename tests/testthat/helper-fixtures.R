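# Shared fixture builders (all data generated in code).

# small, quick simulated recording with known ground truth
quick_sim <- function(seed = 42, duration_s = 8, grid = c(4, 4),
                      fp_rate_per_min = 40, ...) {
  generate_recording(sim_config(grid = grid, duration_s = duration_s,
                                fp_rate_per_min = fp_rate_per_min,
                                seed = seed, ...))
}

# a clean ~15 ms biphasic wavelet of 50 uV peak-trough
fp_wavelet_for_test <- function(fs) fpquant:::fp_wavelet(0.015, fs, 50)

# random multi-channel spike table for super-channel tests; pt amplitudes
# are distinct so partitions can be compared set-wise
random_spike_table <- function(n_spikes, n_channels = 4, span = 1000) {
  onset <- sort(sample.int(span, n_spikes))
  len <- sample(3:40, n_spikes, replace = TRUE)
  data.frame(onset_i = onset, offset_i = onset + len,
             peak_i = onset + pmax(1L, len %/% 2L),
             peak_uV = 0, trough_uV = 0,
             pt_amp_uV = sample.int(10000, n_spikes),
             noise_band_uV = runif(n_spikes, 1, 5),
             channel_id = sprintf("ch%02d", sample.int(n_channels, n_spikes,
                                                       replace = TRUE)),
             stringsAsFactors = FALSE) -> sp
  sp$channel_idx <- as.integer(sub("ch", "", sp$channel_id))
  sp
}

# corpus of hand-built event tables in which true FPs sit at ~9x the local
# noise band and artefact events at 2-6.5x, so the ideal linear coefficient
# is known by construction
constructed_event_corpus <- function(n_rec = 10, seed = 99) {
  set.seed(seed)
  lapply(seq_len(n_rec), function(i) {
    nb <- runif(1, 2, 8)
    n_true <- 20; n_art <- 30
    n <- n_true + n_art
    times <- seq(1, by = 1.05, length.out = n) + runif(n, 0, 0.5)
    ratio <- sample(c(runif(n_true, 8.8, 9.2), runif(n_art, 2, 6.5)))
    ev <- make_event_table(times, pt_amp_uV = ratio * nb,
                           noise_band_uV = nb)
    list(events = ev, peaks = times[ratio > 8])
  })
}
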