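#' Multichannel surface-EMG grid recording
#'
#' Container for a high-density surface EMG recording: an amplitude matrix
#' (channels x samples, microvolts), the sampling rate, and the electrode
#' grid geometry.  Channels may be a subset of the full grid, in which case
#' each channel carries an explicit (row, col) position.
#'
#' @param samples numeric matrix, channels x samples, amplitudes in uV.
#' @param fs sampling rate in Hz.
#' @param grid integer vector `c(rows, cols)` of the electrode layout.
#' @param channel_ids optional character vector of channel labels; defaults
#'   to `ch01`, `ch02`, ...
#' @param positions optional integer matrix (n_channels x 2) of (row, col)
#'   grid positions; defaults to row-major filling when the channel count
#'   equals `rows * cols`.
#' @param meta free-form provenance list.
#' @return an object of class `grid_recording` with fields `samples`, `fs`,
#'   `grid`, `channel_ids`, `positions`, `meta` and derived `duration_s`.
#' @export
grid_recording <- function(samples, fs, grid, channel_ids = NULL,
                           positions = NULL, meta = list()) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), is.numeric(samples))
  stop_if_not_scalar_pos(fs, "fs")
  grid <- as.integer(grid)
  stopifnot(length(grid) == 2L, all(grid >= 0L))
  n_ch <- nrow(samples)
  if (n_ch > prod(grid)) {
    stop("more channels than grid positions", call. = FALSE)
  }
  if (is.null(positions)) {
    if (n_ch != prod(grid) && n_ch > 0L) {
      stop("positions must be given when channels are a subset of the grid",
           call. = FALSE)
    }
    positions <- cbind(rep(seq_len(grid[1L]), each = grid[2L]),
                       rep(seq_len(grid[2L]), times = grid[1L]))[seq_len(n_ch), ,
                                                                 drop = FALSE]
  }
  positions <- matrix(as.integer(positions), ncol = 2L)
  stopifnot(nrow(positions) == n_ch)
  if (n_ch > 0L) {
    stopifnot(all(positions[, 1L] >= 1L), all(positions[, 1L] <= grid[1L]),
              all(positions[, 2L] >= 1L), all(positions[, 2L] <= grid[2L]))
    if (anyDuplicated(positions)) stop("duplicate grid positions", call. = FALSE)
  }
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%02d", seq_len(n_ch))
  stopifnot(length(channel_ids) == n_ch)
  structure(
    list(samples = samples, fs = fs, grid = grid,
         channel_ids = as.character(channel_ids), positions = positions,
         duration_s = ncol(samples) / fs, meta = meta),
    class = "grid_recording"
  )
}

#' @export
print.grid_recording <- function(x, ...) {
  cat(sprintf(
    "grid_recording: %d channel(s) on a %dx%d grid, %.3f s at %g Hz\n",
    nrow(x$samples), x$grid[1L], x$grid[2L], x$duration_s, x$fs))
  if (nrow(x$samples) > 0L) {
    rng <- range(x$samples)
    cat(sprintf("  amplitude range: [%.2f, %.2f] uV\n", rng[1L], rng[2L]))
  }
  invisible(x)
}

#' Number of channels in a recording
#' @param rec a [grid_recording].
#' @return integer channel count.
#' @export
n_channels <- function(rec) nrow(rec$samples)

#' Read an HDSEMG recording
#'
#' Reads either a 16-bit EDF file or a delimited numeric matrix (channels x
#' samples) with a JSON sidecar carrying the sampling metadata.  The sidecar
#' for `path` is `path` with a `.json` extension appended and must contain
#' keys `fs_hz`, `grid_rows`, `grid_cols` and optionally `channel_ids`,
#' `positions` (n x 2) and `units` (must be `"uV"` when present).
#'
#' @param path file path.
#' @param format `"matrix"` or `"edf"`.
#' @param sidecar optional explicit sidecar path (matrix format only).
#' @return a [grid_recording].
#' @export
read_recording <- function(path, format = c("matrix", "edf"), sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edf") return(read_edf(path))
  if (is.null(sidecar)) sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("sidecar metadata not found: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::fromJSON(sidecar)
  for (key in c("fs_hz", "grid_rows", "grid_cols")) {
    if (is.null(meta[[key]])) stop("sidecar missing key: ", key, call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  mat <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  dimnames(mat) <- NULL
  positions <- if (!is.null(meta$positions)) matrix(as.integer(as.matrix(meta$positions)), ncol = 2L)
  if (!is.null(meta$units) && !identical(meta$units, "uV")) {
    stop("unsupported units: ", meta$units, call. = FALSE)
  }
  grid_recording(mat, fs = meta$fs_hz, grid = c(meta$grid_rows, meta$grid_cols),
                 channel_ids = meta$channel_ids, positions = positions,
                 meta = list(source = path))
}

#' Write an HDSEMG recording
#'
#' Inverse of [read_recording()]: `"matrix"` writes a tab-delimited channels
#' x samples table plus a JSON sidecar; `"edf"` writes a 16-bit EDF file.
#'
#' @param rec a [grid_recording].
#' @param path output path; the matrix sidecar is written to `path` + `.json`.
#' @param format `"matrix"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("matrix", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "grid_recording"))
  if (format == "edf") return(write_edf(rec, path))
  utils::write.table(rec$samples, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- list(fs_hz = rec$fs, grid_rows = rec$grid[1L],
                  grid_cols = rec$grid[2L], channel_ids = rec$channel_ids,
                  positions = rec$positions, units = "uV")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# ---- minimal continuous EDF I/O ---------------------------------------------
# Standard European Data Format: 256-byte header + 256 bytes per signal, then
# little-endian int16 data records.  One data record per second, so whole-
# second recordings are required.  Grid geometry is stored in the reserved
# header field ("grid=RxC") and per-channel positions in the per-signal
# reserved fields ("pos=r,c").

pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

#' @rdname read_recording
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  rd(8 + 80 + 80 + 8 + 8 + 8) # version, ids, date, time, header bytes
  reserved <- trimws(rd(44))
  n_records <- as.integer(trimws(rd(8)))
  record_dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "") # transducer
  vapply(seq_len(ns), function(i) rd(8), "")  # dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "") # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  sig_res <- vapply(seq_len(ns), function(i) trimws(rd(32)), "")
  if (length(unique(spr)) != 1L) stop("channels disagree on sampling rate", call. = FALSE)
  fs <- spr[1L] / record_dur
  n <- n_records * spr[1L]
  out <- matrix(0, ns, n)
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  offset <- pmax_ - scale * dmax_
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", spr[s], size = 2L, endian = "little")
      out[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- d * scale[s] + offset[s]
    }
  }
  grid <- c(NA_integer_, NA_integer_)
  gm <- regmatches(reserved, regexec("grid=([0-9]+)x([0-9]+)", reserved))[[1L]]
  if (length(gm) == 3L) grid <- as.integer(gm[2:3])
  pm <- regmatches(sig_res, regexec("pos=([0-9]+),([0-9]+)", sig_res))
  positions <- t(vapply(pm, function(m) as.integer(m[2:3]), integer(2L)))
  grid_recording(out, fs = fs, grid = grid, channel_ids = labels,
                 positions = positions, meta = list(source = path))
}

#' @rdname write_recording
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "grid_recording"))
  fs <- rec$fs
  n <- ncol(rec$samples)
  if (abs(n / fs - round(n / fs)) > 1e-9 || fs != round(fs)) {
    stop("EDF writer requires an integer sampling rate and whole-second duration",
         call. = FALSE)
  }
  ns <- nrow(rec$samples)
  n_records <- as.integer(round(n / fs))
  # physical range is written into 8-char ascii header fields, so round it
  # to 4 significant digits and scale with the *rounded* value to keep the
  # round trip exact up to int16 quantisation
  pmax_ <- apply(abs(rec$samples), 1L, max)
  pmax_[pmax_ == 0] <- 1
  # inflate slightly before rounding so the stored range always covers the
  # data (otherwise int16 overflow would wrap the extreme samples)
  pmax_ <- pmax(signif(pmax_ * 1.001, 4L), 0.01)
  dmax_ <- 32767L
  dig <- pmin(pmax(round(rec$samples / pmax_ * dmax_), -dmax_), dmax_)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeBin(charToRaw(pad(x, width)), con)
  wr("0", 8); wr("synthetic", 80); wr("fpquant", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8)
  wr(sprintf("grid=%dx%d", rec$grid[1L], rec$grid[2L]), 44)
  wr(n_records, 8); wr(format(1L), 8); wr(ns, 4)
  for (i in seq_len(ns)) wr(rec$channel_ids[i], 16)
  for (i in seq_len(ns)) wr("HDSEMG electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  fmt8 <- function(x) {
    s <- formatC(x, format = "fg", digits = 4L)
    if (nchar(s) > 8L) stop("physical range does not fit EDF header", call. = FALSE)
    s
  }
  for (i in seq_len(ns)) wr(fmt8(-pmax_[i]), 8)
  for (i in seq_len(ns)) wr(fmt8(pmax_[i]), 8)
  for (i in seq_len(ns)) wr(-dmax_, 8)
  for (i in seq_len(ns)) wr(dmax_, 8)
  for (i in seq_len(ns)) wr("BP:20-500Hz", 80)
  for (i in seq_len(ns)) wr(as.integer(fs), 8)
  for (i in seq_len(ns)) {
    wr(sprintf("pos=%d,%d", rec$positions[i, 1L], rec$positions[i, 2L]), 32)
  }
  for (r in seq_len(n_records)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      writeBin(as.integer(dig[s, idx]), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
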