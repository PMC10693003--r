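# Classed conditions so callers (and tests) can distinguish user errors.
# Every error raised by the package carries class "metamp_error" plus a
# specific subclass such as "metamp_invalid_parameter".

metamp_abort <- function(message, class) {
  stop(structure(
    class = c(class, "metamp_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# FNV-1a 32-bit hash of a character vector, returned as 8 hex digits.
# Used to stamp resolved scenario configurations into output files.
# Modular arithmetic on doubles (exact below 2^53) because bitwXor()
# only takes values below 2^31.
config_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256 # xor with an 8-bit value only touches the low byte
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  # h < 2^32 may exceed .Machine$integer.max; format the two halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
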