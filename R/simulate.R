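# Seedable synthetic HDSEMG generator with ground truth.  Emulates the
# statistical structure the pipeline assumes: per-channel band-limited
# baseline noise with noise bands in the low-microvolt range, focal
# biphasic/triphasic FP wavelets with spatial decay across the grid,
# transient broad-band noise bursts, and regular voluntary-activity trains.

#' Simulation configuration
#'
#' Defaults mirror the acquisition conditions the pipeline targets: a 2048
#' Hz 8x8 grid, per-channel baseline noise bands of 2-8 uV, 50 FPs/min with
#' focal peak-trough amplitudes log-normally distributed around ~10x the
#' local noise band, wavelet durations of 5-20 ms, and exponential spatial
#' decay across electrodes.
#'
#' @param fs sampling rate in Hz.
#' @param grid electrode layout `c(rows, cols)`.
#' @param duration_s recording length in seconds.
#' @param noise_band_range_uV range the per-channel baseline noise-band
#'   targets are drawn from (uniform).
#' @param fp_rate_per_min expected FP rate; FP times follow a Poisson
#'   process with a 120 ms refractory gap (mean rate preserved).
#' @param fp_amp_meanlog,fp_amp_sdlog log-normal parameters of the FP
#'   peak-trough amplitude as a *ratio* to the focal channel's noise band.
#' @param fp_dur_range_ms wavelet duration range (uniform draw).
#' @param fp_spatial_decay exponential space constant in electrode units.
#' @param fp_triphasic_prob probability an FP is triphasic instead of
#'   biphasic.
#' @param bursts optional data frame (`start_s`, `dur_s`, `amp_uV`) of
#'   broad-band noise bursts added to every channel; FPs are kept disjoint
#'   from burst intervals.
#' @param voluntary optional data frame (`start_s`, `n_events`, `ifi_ms`,
#'   `amp_ratio`) of regular voluntary-activity trains.
#' @param require_fps error (instead of proceeding) when the expected FP
#'   count is below 1.
#' @param seed integer seed fixing all randomness; `NULL` leaves the RNG
#'   state untouched.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(fs = 2048, grid = c(8, 8), duration_s = 60,
                       noise_band_range_uV = c(2, 8), fp_rate_per_min = 50,
                       fp_amp_meanlog = log(10), fp_amp_sdlog = 0.3,
                       fp_dur_range_ms = c(5, 20), fp_spatial_decay = 1.5,
                       fp_triphasic_prob = 0.25, bursts = NULL,
                       voluntary = NULL, require_fps = FALSE, seed = NULL) {
  stop_if_not_scalar_pos(fs, "fs")
  stop_if_not_scalar_pos(duration_s, "duration_s")
  stopifnot(length(grid) == 2L, all(grid >= 1),
            length(noise_band_range_uV) == 2L, all(noise_band_range_uV > 0),
            fp_rate_per_min >= 0, fp_amp_sdlog >= 0,
            all(fp_dur_range_ms > 0), fp_spatial_decay > 0,
            fp_triphasic_prob >= 0, fp_triphasic_prob <= 1)
  if (require_fps && fp_rate_per_min * duration_s / 60 < 1) {
    stop("infeasible config: expected FP count below 1", call. = FALSE)
  }
  structure(list(fs = fs, grid = as.integer(grid), duration_s = duration_s,
                 noise_band_range_uV = noise_band_range_uV,
                 fp_rate_per_min = fp_rate_per_min,
                 fp_amp_meanlog = fp_amp_meanlog, fp_amp_sdlog = fp_amp_sdlog,
                 fp_dur_range_ms = fp_dur_range_ms,
                 fp_spatial_decay = fp_spatial_decay,
                 fp_triphasic_prob = fp_triphasic_prob,
                 bursts = bursts, voluntary = voluntary,
                 require_fps = require_fps, seed = seed),
            class = "sim_config")
}

# smooth multi-lobe wavelet with deliberately unequal lobe amplitudes so the
# absolute maximum (the ground-truth peak) is unambiguous; rescaled so the
# discrete peak-trough amplitude is exactly `amp`
fp_wavelet <- function(dur_s, fs, amp, triphasic = FALSE, polarity = 1) {
  s <- dur_s / 5.6
  sigma <- 0.6 * s
  tt <- seq(-2.8 * s, 2.8 * s, by = 1 / fs)
  w <- if (triphasic) {
    0.5 * exp(-(tt + 1.6 * s)^2 / (2 * sigma^2)) -
      0.35 * exp(-tt^2 / (2 * sigma^2)) +
      0.2 * exp(-(tt - 1.6 * s)^2 / (2 * sigma^2))
  } else {
    0.65 * exp(-(tt + s)^2 / (2 * sigma^2)) -
      0.35 * exp(-(tt - s)^2 / (2 * sigma^2))
  }
  w <- polarity * w * amp / (max(w) - min(w))
  w
}

# scale a channel so its realised noise band (mean positive minus mean
# negative amplitude) hits the target
scale_to_noise_band <- function(x, target) {
  nb <- mean(x[x > 0]) - mean(x[x < 0])
  x * target / nb
}

#' Generate one synthetic HDSEMG recording with ground truth
#'
#' Baseline noise is white Gaussian noise bandpassed to 20-500 Hz and
#' scaled per channel so the realised noise band matches its target.  FPs
#' are injected as focal wavelets with exponential spatial decay across the
#' grid; noise bursts and voluntary trains are added when configured.
#'
#' @param cfg a [sim_config()].
#' @return list with `recording` (a [grid_recording]) and `truth`, a list
#'   holding `fp_peak_times_s`, `fp_origin_channels`, `fp_amplitudes_uV`,
#'   `noise_band_target_uV`, `voluntary_intervals` and `burst_intervals`.
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fs <- cfg$fs
  n <- as.integer(round(cfg$duration_s * fs))
  rows <- cfg$grid[1L]; cols <- cfg$grid[2L]
  n_ch <- rows * cols
  positions <- cbind(rep(seq_len(rows), each = cols),
                     rep(seq_len(cols), times = rows))
  bf <- signal::butter(4, c(20, 500) / (fs / 2), type = "pass")
  targets <- stats::runif(n_ch, cfg$noise_band_range_uV[1L],
                          cfg$noise_band_range_uV[2L])
  x <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    v <- signal::filtfilt(bf, stats::rnorm(n))
    x[ch, ] <- scale_to_noise_band(v, targets[ch])
  }

  burst_intervals <- data.frame(start_s = numeric(), end_s = numeric())
  if (!is.null(cfg$bursts) && nrow(cfg$bursts)) {
    for (i in seq_len(nrow(cfg$bursts))) {
      b <- cfg$bursts[i, ]
      i1 <- max(1L, as.integer(round(b$start_s * fs)) + 1L)
      i2 <- min(n, as.integer(round((b$start_s + b$dur_s) * fs)))
      if (i2 <= i1) next
      for (ch in seq_len(n_ch)) {
        v <- signal::filtfilt(bf, stats::rnorm(i2 - i1 + 1L))
        x[ch, i1:i2] <- x[ch, i1:i2] + scale_to_noise_band(v, b$amp_uV)
      }
      burst_intervals <- rbind(burst_intervals,
                               data.frame(start_s = (i1 - 1L) / fs,
                                          end_s = i2 / fs))
    }
  }

  # FP times: Poisson process with a 120 ms refractory gap, mean rate kept
  edge <- 0.25
  fp_times <- numeric(0)
  if (cfg$fp_rate_per_min > 0) {
    mean_gap <- 60 / cfg$fp_rate_per_min
    refractory <- 0.12
    exp_rate <- 1 / max(mean_gap - refractory, 1e-3)
    t <- edge
    repeat {
      t <- t + refractory + stats::rexp(1L, exp_rate)
      if (t > cfg$duration_s - edge) break
      fp_times <- c(fp_times, t)
    }
    if (nrow(burst_intervals)) {
      inside <- vapply(fp_times, function(tt) {
        any(tt >= burst_intervals$start_s & tt < burst_intervals$end_s)
      }, logical(1L))
      fp_times <- fp_times[!inside]
    }
  }

  inject <- function(center_s, origin, amp, dur_s, triphasic, polarity) {
    w <- fp_wavelet(dur_s, fs, amp, triphasic, polarity)
    half <- (length(w) - 1L) %/% 2L
    c0 <- as.integer(round(center_s * fs)) + 1L
    i1 <- c0 - half
    i2 <- i1 + length(w) - 1L
    if (i1 < 1L || i2 > n) return(NA_real_)
    d <- sqrt((positions[, 1L] - positions[origin, 1L])^2 +
                (positions[, 2L] - positions[origin, 2L])^2)
    gain <- exp(-d / cfg$fp_spatial_decay)
    for (ch in seq_len(n_ch)) {
      x[ch, i1:i2] <<- x[ch, i1:i2] + gain[ch] * w
    }
    (i1 + which.max(abs(w)) - 2L) / fs  # realised peak time of the wavelet
  }

  fp_origin <- integer(0); fp_amp <- numeric(0); fp_peak <- numeric(0)
  for (tt in fp_times) {
    origin <- sample.int(n_ch, 1L)
    ratio <- stats::rlnorm(1L, cfg$fp_amp_meanlog, cfg$fp_amp_sdlog)
    amp <- ratio * targets[origin]
    dur_s <- stats::runif(1L, cfg$fp_dur_range_ms[1L],
                          cfg$fp_dur_range_ms[2L]) / 1000
    tri <- stats::runif(1L) < cfg$fp_triphasic_prob
    pol <- sample(c(-1, 1), 1L)
    pk <- inject(tt, origin, amp, dur_s, tri, pol)
    if (is.na(pk)) next
    fp_origin <- c(fp_origin, origin)
    fp_amp <- c(fp_amp, amp)
    fp_peak <- c(fp_peak, pk)
  }

  voluntary_intervals <- data.frame(start_s = numeric(), end_s = numeric())
  if (!is.null(cfg$voluntary) && nrow(cfg$voluntary)) {
    for (i in seq_len(nrow(cfg$voluntary))) {
      v <- cfg$voluntary[i, ]
      origin <- sample.int(n_ch, 1L)
      times <- v$start_s + (seq_len(v$n_events) - 1L) * v$ifi_ms / 1000
      for (tt in times) {
        inject(tt, origin, v$amp_ratio * targets[origin], 0.01, FALSE, 1)
      }
      voluntary_intervals <- rbind(voluntary_intervals,
                                   data.frame(start_s = times[1L],
                                              end_s = times[length(times)]))
    }
  }

  ord <- order(fp_peak)
  rec <- grid_recording(x, fs = fs, grid = cfg$grid, positions = positions,
                        meta = list(simulated = TRUE, seed = cfg$seed))
  list(recording = rec,
       truth = list(fp_peak_times_s = fp_peak[ord],
                    fp_origin_channels = rec$channel_ids[fp_origin[ord]],
                    fp_amplitudes_uV = fp_amp[ord],
                    noise_band_target_uV = targets,
                    voluntary_intervals = voluntary_intervals,
                    burst_intervals = burst_intervals))
}

#' Generate a corpus of annotated synthetic recordings
#'
#' Draws `n_recordings` recordings whose baseline noise scales spread
#' multiplicatively around the base configuration (log-normal factor with
#' SD `heterogeneity`), emulating noise differences between muscles and
#' visits.  Manual-style annotations are derived from the ground-truth FP
#' peaks, optionally degraded with miss and false-annotation rates.
#'
#' @param base_cfg a [sim_config()] used for every recording (its `seed` is
#'   ignored; per-recording seeds are drawn from `seed`).
#' @param n_recordings number of recordings (>= 2).
#' @param heterogeneity SD of the log-normal noise-scale factor across
#'   recordings; 0 gives a homogeneous corpus.
#' @param annotation_miss_rate probability a true FP peak is missing from
#'   the annotation.
#' @param annotation_false_rate expected false annotations per true FP.
#' @param seed integer seed for the whole corpus.
#' @return list of elements `list(recording, truth, annotation)` where
#'   `annotation` has `recording_id`, `peak_times_s` and `window_s`.
#' @export
generate_corpus <- function(base_cfg, n_recordings, heterogeneity = 0.5,
                            annotation_miss_rate = 0,
                            annotation_false_rate = 0, seed = 1) {
  stopifnot(inherits(base_cfg, "sim_config"), n_recordings >= 2L)
  set.seed(seed)
  factors <- exp(stats::rnorm(n_recordings, 0, heterogeneity))
  rec_seeds <- sample.int(2^30, n_recordings)
  lapply(seq_len(n_recordings), function(i) {
    corpus_element(base_cfg, factors[i], rec_seeds[i], i,
                   annotation_miss_rate, annotation_false_rate)
  })
}

# one corpus recording: scaled noise, seeded generation, degraded annotation
corpus_element <- function(base_cfg, factor, rec_seed, i,
                           annotation_miss_rate, annotation_false_rate) {
  cfg <- base_cfg
  cfg$noise_band_range_uV <- base_cfg$noise_band_range_uV * factor
  cfg$seed <- rec_seed
  sim <- generate_recording(cfg)
  peaks <- sim$truth$fp_peak_times_s
  if (annotation_miss_rate > 0 && length(peaks)) {
    peaks <- peaks[stats::runif(length(peaks)) >= annotation_miss_rate]
  }
  if (annotation_false_rate > 0) {
    n_false <- stats::rpois(1L, annotation_false_rate *
                              length(sim$truth$fp_peak_times_s))
    peaks <- sort(c(peaks, stats::runif(n_false, 0, cfg$duration_s)))
  }
  list(recording = sim$recording, truth = sim$truth,
       annotation = list(recording_id = sprintf("rec%03d", i),
                         peak_times_s = peaks,
                         window_s = cfg$duration_s))
}
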