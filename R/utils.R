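# Internal helpers shared across modules.

# Run `code` under a local RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` means "use the current stream".
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic per-participant sub-seed from a master seed and a counter.
# Linear-congruential style mixing, kept below 2^31 - 1 so the result is a
# valid R integer seed.
derive_seed <- function(master, index, stream = 0L) {
  m <- 2147483647
  s <- (as.numeric(master) %% m)
  s <- (s * 48271 + 7919 * as.numeric(index) + 104729 * as.numeric(stream)) %% m
  as.integer(s)
}

# Wall-distance denominators are clamped at this floor before division so
# responses placed exactly on a wall yield a finite, loggable ratio.
CLAMP_FLOOR <- 0.1

# Clamp a vector of denominators at `floor`. Clamp events are loggable:
# a warning carries their count.
clamp_denominator <- function(d, floor = CLAMP_FLOOR, warn = TRUE) {
  n <- sum(d < floor)
  if (n > 0L && warn) {
    warning(sprintf("%d wall-distance denominator(s) below %g vm clamped", n, floor),
            call. = FALSE)
  }
  pmax(d, floor)
}

# Rolling polynomial hash of a character vector, returned as 8 hex digits.
# Used to stamp pipeline outputs with a config fingerprint (not cryptographic).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 4294967296
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
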