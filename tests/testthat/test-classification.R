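test_that("inclusion threshold arithmetic follows the model family", {
  lin <- threshold_model("linear", 8)
  expect_equal(at_inc(lin, 5), 40)
  expect_equal(at_inc(lin, 0), 0)
  expect_equal(at_inc(threshold_model("constant", 30), 12), 30)
  expect_equal(at_inc(lin, c(1, 2, 3)), c(8, 16, 24))
  expect_error(at_inc(lin, -1), "negative")
  expect_error(threshold_model("linear", -3))
})

test_that("events are labelled by strict comparison against their own threshold", {
  ev <- make_event_table(c(1, 2), pt_amp_uV = c(50, 30), noise_band_uV = c(5, 5))
  cls <- classify_events(ev, threshold_model("linear", 8))
  expect_equal(cls$label, c("fp", "subthreshold")) # 50 > 40, 30 <= 40
  expect_equal(cls$at_inc_uV, c(40, 40))
  # boundary: exactly at the threshold is NOT included
  ev2 <- make_event_table(1, pt_amp_uV = 40, noise_band_uV = 5)
  expect_equal(classify_events(ev2, threshold_model("linear", 8))$label,
               "subthreshold")
})

test_that("classification matches per-event brute comparison on a fixture", {
  set.seed(51)
  n <- 200
  nb <- runif(n, 1, 8)
  amp <- nb * runif(n, 4, 12)
  ev <- make_event_table(seq_len(n), pt_amp_uV = amp, noise_band_uV = nb)
  cls <- classify_events(ev, threshold_model("linear", 8))
  expect_equal(cls$label == "fp", amp > 8 * nb)
})

test_that("block exclusion applies the majority and double-threshold rules", {
  mk <- function(at_inc, peak_s) {
    ev <- make_event_table(peak_s, pt_amp_uV = 1, noise_band_uV = 1)
    ev$at_inc_uV <- at_inc
    ev$label <- "fp"
    ev
  }
  # (a) majority: 2/3 spikes over the exclusion threshold
  r1 <- exclude_noisy_blocks(mk(c(120, 110, 40), c(1, 2, 3)), 60)
  expect_equal(nrow(r1$blocks), 1L)
  expect_equal(r1$blocks$reason, "majority_over_atexc")
  expect_equal(r1$blocks[, c("start_s", "end_s")],
               data.frame(start_s = 0, end_s = 5))
  expect_true(all(r1$events$label == "excluded_block"))
  # (b) a single spike over twice the threshold
  r2 <- exclude_noisy_blocks(mk(250, 2), 60)
  expect_equal(r2$blocks$reason, "single_over_2x_atexc")
  # neither rule fires: 1/3 is not a majority and none exceeds 200
  r3 <- exclude_noisy_blocks(mk(c(90, 95, 120), c(1, 2, 3)), 60)
  expect_equal(nrow(r3$blocks), 0L)
  expect_true(all(r3$events$label == "fp"))
  # events in other blocks are untouched
  r4 <- exclude_noisy_blocks(mk(c(250, 30), c(2, 12)), 60)
  expect_equal(r4$events$label, c("excluded_block", "fp"))
  # disabling the threshold disables exclusion
  expect_equal(nrow(exclude_noisy_blocks(mk(500, 1), 60, at_exc = "off")$blocks), 0L)
})

test_that("voluntary trains of >= 4 closely spaced FPs are relabelled", {
  mk <- function(peaks_ms) {
    ev <- make_event_table(peaks_ms / 1000, pt_amp_uV = 50, noise_band_uV = 2,
                           width_s = 0.005)
    ev$label <- "fp"
    ev
  }
  expect_equal(flag_voluntary(mk(c(0, 100, 200, 300)))$label,
               rep("voluntary", 4))
  expect_equal(flag_voluntary(mk(c(0, 100, 200)))$label, rep("fp", 3))
  expect_equal(flag_voluntary(mk(c(0, 300, 600, 900)))$label, rep("fp", 4))
  # a 250 ms gap is not < 250 ms
  expect_equal(flag_voluntary(mk(c(0, 250, 500, 750)))$label, rep("fp", 4))
  # run of 5 with one long gap inside: only the 4-run is voluntary
  out <- flag_voluntary(mk(c(0, 100, 200, 300, 900)))
  expect_equal(out$label, c(rep("voluntary", 4), "fp"))
})

test_that("summary arithmetic reproduces the worked frequency adjustment", {
  set.seed(52)
  ev <- make_event_table(sort(runif(369, 5.1, 59.9)), pt_amp_uV = 60,
                         noise_band_uV = 2, width_s = 0.002)
  ev$label <- "fp"
  blocks <- data.frame(start_s = 0, end_s = 5, reason = "majority_over_atexc",
                       n_spikes = 0L)
  s <- summarise_recording(ev, 60, blocks)
  expect_equal(s$fp_count, 369L)
  expect_equal(s$analysed_time_min, 55 / 60)
  expect_equal(round(s$analysed_time_min, 3), 0.917)
  expect_equal(s$fp_freq_rounded, 403)

  s0 <- summarise_recording(ev[0, ], 60)
  expect_equal(s0$fp_freq_per_min, 0)
  ev30 <- make_event_table(seq(0.5, 29.5, length.out = 30), 60, 2,
                           width_s = 0.002)
  ev30$label <- "fp"
  expect_equal(summarise_recording(ev30, 30)$fp_freq_per_min, 60)
  expect_error(summarise_recording(ev, 5, data.frame(start_s = 0, end_s = 5)),
               "undefined")
})

test_that("every event keeps exactly one label and counts partition", {
  sim <- quick_sim(seed = 53, duration_s = 8)
  proc <- process_recording(sim$recording, inner_grid = FALSE,
                            exclude_bad = FALSE)
  ev <- classify_events(proc$events, threshold_model("linear", 8))
  ex <- exclude_noisy_blocks(ev, sim$recording$duration_s)
  ev2 <- flag_voluntary(ex$events)
  expect_true(all(ev2$label %in% c("fp", "subthreshold", "excluded_block",
                                   "voluntary")))
  expect_equal(sum(table(ev2$label)), nrow(ev2))
})

test_that("FP count is monotone non-increasing in the threshold coefficient", {
  sim <- quick_sim(seed = 54, duration_s = 8)
  proc <- process_recording(sim$recording, inner_grid = FALSE,
                            exclude_bad = FALSE)
  count_at <- function(kind, coefs) {
    vapply(coefs, function(a) {
      sum(classify_events(proc$events, threshold_model(kind, a))$label == "fp")
    }, numeric(1))
  }
  expect_true(all(diff(count_at("linear", c(2, 4, 6, 8, 10, 12))) <= 0))
  expect_true(all(diff(count_at("constant", c(10, 20, 40, 60, 100))) <= 0))
})

test_that("noise-responsive labels are scale invariant; constant labels are not", {
  sim <- quick_sim(seed = 55, duration_s = 8, fp_rate_per_min = 60)
  rec <- sim$recording
  rec_s <- rec
  rec_s$samples <- rec_s$samples * 4.2
  lab <- function(r, model) {
    proc <- process_recording(r, inner_grid = FALSE, exclude_bad = FALSE)
    classify_events(proc$events, model)$label
  }
  lin <- threshold_model("linear", 8)
  expect_equal(lab(rec, lin), lab(rec_s, lin))
  con <- threshold_model("constant", 30)
  expect_false(identical(lab(rec, con), lab(rec_s, con)))
})

test_that("lowering the exclusion threshold never increases analysed time", {
  sim <- quick_sim(seed = 56, duration_s = 20,
                   bursts = data.frame(start_s = 8, dur_s = 3, amp_uV = 150))
  proc <- process_recording(sim$recording, inner_grid = FALSE,
                            exclude_bad = FALSE)
  ev <- classify_events(proc$events, threshold_model("linear", 8))
  analysed <- vapply(c(400, 100, 50, 25), function(ae) {
    ex <- exclude_noisy_blocks(ev, 20, at_exc = ae)
    summarise_recording(ex$events, 20, ex$blocks)$analysed_time_min
  }, numeric(1))
  expect_true(all(diff(analysed) <= 1e-12))
  off <- exclude_noisy_blocks(ev, 20, at_exc = "off")
  expect_equal(summarise_recording(off$events, 20, off$blocks)$analysed_time_min,
               20 / 60)
})
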