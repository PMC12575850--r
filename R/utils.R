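# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Derive a reproducible 32-bit child seed from a root seed and a stream
# index, so per-cancer-type / per-patient generation is stable under
# subsetting. Plain integer arithmetic; keeps results inside [0, 2^31).
derive_seed <- function(root, index) {
  root <- as.double(root)
  index <- as.double(index)
  x <- (root * 48271 + index * 16807 + 11) %% 2147483647
  # one multiplicative mixing round to decorrelate adjacent indices
  x <- (x * 69621) %% 2147483647
  as.integer(x)
}

# Tiny FNV-1a string hash (hex) used for config fingerprints in run
# manifests; avoids an external digest dependency.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep in int range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

is_scalar_number <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x)
}
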