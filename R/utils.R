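# Internal condition helpers. All errors signalled by the package subclass
# "critfocus_error" so callers can trap them as a family; the specific
# subclasses mirror the failure modes of the detection pipeline.

stop_invalid <- function(msg, ...) {
  abort(msg, class = c("critfocus_error_invalid", "critfocus_error"), ...)
}

stop_out_of_bounds <- function(msg, ...) {
  abort(msg, class = c("critfocus_error_field_out_of_bounds", "critfocus_error"), ...)
}

stop_no_field <- function(msg = "no-field-detected: gradient profile has no rising/falling edge pair") {
  abort(msg, class = c("critfocus_error_no_field", "critfocus_error"))
}

stop_inverted <- function(msg = "inverted-edges: global gradient maximum lies after the global minimum") {
  abort(msg, class = c("critfocus_error_inverted_edges", "critfocus_error"))
}

stop_degenerate <- function(msg) {
  abort(msg, class = c("critfocus_error_degenerate_curve", "critfocus_error"))
}

stop_travel <- function(msg) {
  abort(msg, class = c("critfocus_error_travel_exceeded", "critfocus_error"))
}

stop_format <- function(msg) {
  abort(msg, class = c("critfocus_error_format", "critfocus_error"))
}

stop_io <- function(msg) {
  abort(msg, class = c("critfocus_error_io", "critfocus_error"))
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(sprintf("`%s` must be a single number", name))
  }
  if (finite && !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be finite", name))
  }
  if (positive && x <= 0) {
    stop_invalid(sprintf("`%s` must be strictly positive", name))
  }
  invisible(x)
}

# Deterministic per-frame seed derivation from a master seed. Pure integer
# arithmetic (kept under 2^53 so doubles are exact), folded into [1, 2^31 - 2].
derive_seed <- function(master, index) {
  m <- 2147483629
  ((master %% m) * 48271 + index * 16807) %% m + 1
}

# FNV-1a 32-bit hash of an R object, used to stamp manifests with the
# generating configuration.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # exact 32-bit modular multiply via 16-bit limbs (doubles stay < 2^53)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}
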