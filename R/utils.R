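# Internal helpers: scoped RNG, deterministic seed substreams, tiny hashing.

# Evaluate `expr` under `seed` and restore the caller's RNG state afterwards,
# so library functions never perturb the user's random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a character scalar, reduced to a positive R integer.
# Used to derive named, reproducible seed substreams and config fingerprints.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes %% 256) {
    lo <- h %% 256
    h <- h - lo + bitwXor(lo, b)  # xor touches only the low byte (b < 256)
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # split so every intermediate stays exact in a double
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  h
}

# Deterministic substream seed: combine a root seed with a stream name.
# Result is in [0, 2^31 - 2] so it is always a valid set.seed() input.
derive_seed <- function(root_seed, ...) {
  key <- paste(c(format(root_seed), vapply(list(...), format, "")),
               collapse = "/")
  as.integer((fnv1a32(key) + as.numeric(root_seed)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
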