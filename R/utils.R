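#' @keywords internal
"_PACKAGE"

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FNV-1a 32-bit hash of an R object's deparsed form, as 8 hex characters.
# Used to stamp pipeline outputs with a configuration fingerprint.
# The bitw* family needs values < 2^31, so the arithmetic runs on doubles.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

# 32-bit XOR on doubles holding unsigned ints.
xor32 <- function(a, b) {
  hi_a <- a %/% 2147483648; lo_a <- a %% 2147483648
  hi_b <- b %/% 2147483648; lo_b <- b %% 2147483648
  xhi <- (hi_a + hi_b) %% 2
  xlo <- bitwXor(as.integer(lo_a), as.integer(lo_b))
  xhi * 2147483648 + as.numeric(xlo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
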