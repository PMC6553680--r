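# internal helpers shared across modules

#' Lightweight configuration fingerprint
#'
#' Deterministic 32-bit polynomial hash of an R object's deparsed form,
#' stamped into every output file so that results can be traced back to the
#' exact configuration that produced them.  Not cryptographic.
#'
#' @param x any R object (typically a named list of run parameters).
#' @return an 8-character lowercase hex string.
#' @export
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  m <- 2147483647 # 2^31 - 1
  for (b in bytes) h <- (h * 131 + b) %% m
  sprintf("%08x", h)
}

# round-half-up to integer (display convention for per-minute frequencies)
round_half_up <- function(x) floor(x + 0.5)

# standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name), call. = FALSE)
  }
  invisible(x)
}
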