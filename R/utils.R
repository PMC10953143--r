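# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  code
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# FNV-1a hash of a raw vector, reported as 8 hex digits.  Used to stamp
# pipeline outputs with a configuration fingerprint without external
# dependencies.
fnv1a_hash <- function(raw_bytes) {
  h <- 2166136261
  for (b in as.integer(raw_bytes)) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(lo8, b)
    # 32-bit modular multiply by the FNV prime 16777619, done in two halves
    # to stay within double precision.
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  # h is a double (R integers cannot hold 2^32); format as hex manually
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

config_hash <- function(cfg) {
  fnv1a_hash(charToRaw(yaml::as.yaml(cfg)))
}

# Derive a bounded per-stage seed from a master seed (kept below 2^31).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9176) %% 2147483587L)
}
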