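test_that("matrix + sidecar round trip preserves the recording", {
  set.seed(11)
  rec <- grid_recording(matrix(rnorm(6 * 500), 6, 500), fs = 1000,
                        grid = c(2, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path, format = "matrix")
  back <- read_recording(path, format = "matrix")
  expect_equal(back$samples, rec$samples, tolerance = 1e-6)
  expect_equal(back$fs, 1000)
  expect_equal(back$grid, c(2L, 3L))
  expect_equal(back$channel_ids, rec$channel_ids)
  expect_equal(back$positions, rec$positions)
})

test_that("matrix format supports channel subsets with explicit positions", {
  set.seed(12)
  pos <- cbind(c(2L, 3L, 5L), c(1L, 4L, 8L))
  rec <- grid_recording(matrix(rnorm(3 * 200), 3, 200), fs = 2048,
                        grid = c(8, 8), positions = pos,
                        channel_ids = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$positions, pos)
  expect_equal(back$channel_ids, c("a", "b", "c"))
})

test_that("missing sidecar metadata is a contract violation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(matrix(0, 2, 10), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  expect_error(read_recording(path), "sidecar")
  jsonlite::write_json(list(grid_rows = 1, grid_cols = 2),
                       paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_recording(path), "fs_hz")
})

test_that("EDF round trip reproduces a 64-channel recording to int16 precision", {
  set.seed(13)
  rec <- grid_recording(matrix(rnorm(64 * 2 * 2048, sd = 20), 64, 2 * 2048),
                        fs = 2048, grid = c(8, 8))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$fs, 2048)
  expect_equal(back$grid, c(8L, 8L))
  expect_equal(back$channel_ids, rec$channel_ids)
  expect_equal(back$positions, rec$positions)
  qstep <- max(abs(rec$samples)) / 32767
  expect_lt(max(abs(back$samples - rec$samples)), 1.5 * qstep)
})

test_that("bandpass attenuates out-of-band tones and passes in-band tones", {
  fs <- 2048
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs)
  mid <- seq(fs, 3 * fs) # central window, away from edge transients
  slow <- grid_recording(sin(2 * pi * 5 * tt), fs, c(1, 1))
  fast <- grid_recording(sin(2 * pi * 100 * tt), fs, c(1, 1))
  expect_lt(max(abs(bandpass(slow)$samples[1, mid])), 10^(-20 / 20))
  expect_equal(max(abs(bandpass(fast)$samples[1, mid])), 1, tolerance = 0.05)
  zero <- grid_recording(matrix(0, 1, fs), fs, c(1, 1))
  expect_equal(bandpass(zero)$samples, zero$samples)
  expect_error(bandpass(slow, 20, 2000), "Nyquist")
})

test_that("bandpass is idempotent in the passband and preserves duration", {
  fs <- 2048
  tt <- seq(0, 2 - 1 / fs, by = 1 / fs)
  rec <- grid_recording(sin(2 * pi * 80 * tt) + 0.5 * sin(2 * pi * 200 * tt),
                        fs, c(1, 1))
  once <- bandpass(rec)
  twice <- bandpass(once)
  expect_equal(ncol(once$samples), length(tt))
  mid <- seq(fs / 2, 3 * fs / 2)
  expect_equal(twice$samples[1, mid], once$samples[1, mid], tolerance = 0.02)
})

test_that("inner-grid selection matches the (rows-2)(cols-2) geometry", {
  mk <- function(rows, cols) {
    grid_recording(matrix(0, rows * cols, 10), fs = 100, grid = c(rows, cols))
  }
  expect_equal(n_channels(select_inner_grid(mk(8, 8))), 36L)
  inner3 <- select_inner_grid(mk(3, 3))
  expect_equal(n_channels(inner3), 1L)
  expect_equal(inner3$channel_ids, "ch05") # the centre of a row-major 3x3
  expect_equal(n_channels(select_inner_grid(mk(2, 8))), 0L)
  expect_equal(select_inner_grid(mk(5, 4))$grid, c(3L, 2L))
})

test_that("gross outlier channels are excluded where the CI oracle says so", {
  set.seed(21)
  x <- matrix(rnorm(36 * 4000, sd = 3), 36, 4000)
  x[7, ] <- x[7, ] * 20
  rec <- grid_recording(x, fs = 2000, grid = c(6, 6))
  rep_ <- detect_bad_channels(rec)
  # direct CI oracle on the amplitude range
  ar <- apply(x, 1, function(v) max(v) - min(v))
  hi <- mean(ar) + 1.96 * sd(ar)
  expect_true(all(which(ar > hi) %in% which(rep_$excluded)))
  expect_true(rep_$excluded[7])
  expect_equal(rep_$reason[7], "noisy")
})

test_that("null channels are flagged and every exclusion has one reason", {
  set.seed(22)
  x <- matrix(rnorm(10 * 2000, sd = 3), 10, 2000)
  x[4, ] <- 0
  rec <- grid_recording(x, fs = 2000, grid = c(2, 5))
  rep_ <- detect_bad_channels(rec)
  expect_true(rep_$excluded[4])
  expect_equal(rep_$reason[4], "null")
  expect_true(all(!is.na(rep_$reason[rep_$excluded])))
  expect_true(all(is.na(rep_$reason[!rep_$excluded])))
  expect_equal(attr(rep_, "n_surviving"), sum(!rep_$excluded))
})

test_that("bad-channel detection is invariant to channel ordering", {
  set.seed(23)
  x <- matrix(rnorm(12 * 2000, sd = 3), 12, 2000)
  x[2, ] <- x[2, ] * 15
  rec <- grid_recording(x, fs = 2000, grid = c(3, 4))
  perm <- sample(12)
  rec_p <- grid_recording(x[perm, ], fs = 2000, grid = c(3, 4),
                          positions = rec$positions[perm, ],
                          channel_ids = rec$channel_ids[perm])
  r1 <- detect_bad_channels(rec)
  r2 <- detect_bad_channels(rec_p)
  excl1 <- sort(r1$channel_id[r1$excluded])
  excl2 <- sort(r2$channel_id[r2$excluded])
  expect_equal(excl1, excl2)
})

test_that("homogeneous channels are excluded only at the CI tail rate", {
  frac <- vapply(1:15, function(s) {
    set.seed(s)
    rec <- grid_recording(matrix(rnorm(36 * 1500, sd = 3), 36, 1500),
                          fs = 1500, grid = c(6, 6))
    mean(detect_bad_channels(rec)$excluded)
  }, numeric(1))
  expect_lt(mean(frac), 0.15)
})
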