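# Classed error conditions so callers (and tests) can distinguish a bad
# configuration from bad data or a missing file.

abort_ctc <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ctcgate_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_config <- function(message) abort_ctc(message, "ctcgate_config_error")
stop_validation <- function(message) abort_ctc(message, "ctcgate_validation_error")
stop_lookup <- function(message) abort_ctc(message, "ctcgate_lookup_error")
stop_degenerate <- function(message) abort_ctc(message, "ctcgate_degenerate_error")
stop_capacity <- function(message) abort_ctc(message, "ctcgate_capacity_error")
stop_layout <- function(message) abort_ctc(message, "ctcgate_layout_error")
stop_pairing <- function(message) abort_ctc(message, "ctcgate_pairing_error")

#' Flagged-undefined value
#'
#' Ratios with an empty denominator (for example the false-positive fraction
#' of a sample with no standard-identified CTCs) are reported as `NA` carrying
#' a `reason` attribute, never as zero, so batch means are not silently
#' skewed.
#'
#' @param reason short explanation of why the value is undefined.
#' @return `NA_real_` with attributes `flagged = TRUE` and `reason`.
#' @export
flagged_na <- function(reason) {
  structure(NA_real_, flagged = TRUE, reason = reason)
}

#' Test whether a value is a flagged-undefined result
#' @param x a value returned by a summary operation.
#' @return `TRUE` if `x` is a [flagged_na()] result.
#' @export
is_flagged <- function(x) isTRUE(attr(x, "flagged"))

# 32-bit FNV-1a over a string; used for provenance hashes of configurations
# (no cryptographic requirement, just a stable short fingerprint).
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    # xor affects only the low byte (b < 256); keep h a double in [0, 2^32)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619, split into 16-bit
    # halves so intermediate products stay inside double precision
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  # format as hex from the two 16-bit halves (h may exceed .Machine integers)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Derive a 32-bit sub-seed from a base seed and a stream label, so placement,
# intensities and noise use distinct reproducible streams.
derive_seed <- function(seed, stream) {
  h <- fnv1a32(paste0(stream, ":", seed))
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}
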