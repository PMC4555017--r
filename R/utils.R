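# Low-level word/byte helpers. Every multi-byte integer field in the stream
# format and the packet format is little-endian; these helpers are the single
# place that convention lives.
#
# 16-bit words are carried as R integers (0..65535). 32- and 64-bit unsigned
# fields are carried as R doubles, which are exact for integers below 2^53 —
# comfortably above the 2^32 counters and UNIX-seconds experiment ids used
# here.

# integer 16-bit words -> raw bytes (little-endian)
wordsToRaw <- function(w) {
  w <- as.integer(w)
  as.raw(as.vector(rbind(w %% 256L, w %/% 256L)))
}

# raw bytes -> integer 16-bit words (little-endian); length(r) must be even
rawToWords <- function(r) {
  b <- as.integer(r)
  n <- length(b)
  if (n %% 2L != 0L) stop("odd byte count cannot form 16-bit words")
  b[seq.int(1L, n, 2L)] + 256L * b[seq.int(2L, n, 2L)]
}

# unsigned 32-bit value(s) -> 2 x n matrix of 16-bit words, low word first
u32ToWords <- function(x) {
  rbind(x %% 65536, x %/% 65536)
}

# unsigned 64-bit value(s) -> 4 x n matrix of 16-bit words, low word first
u64ToWords <- function(x) {
  w1 <- x %% 65536; x <- x %/% 65536
  w2 <- x %% 65536; x <- x %/% 65536
  rbind(w1, w2, x %% 65536, x %/% 65536)
}

wordsToU32 <- function(lo, hi) lo + 65536 * hi

wordsToU64 <- function(w1, w2, w3, w4) {
  w1 + 65536 * (w2 + 65536 * (w3 + 65536 * w4))
}

stopifnotU16 <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 65535) || any(x != floor(x)))
    stop(what, " must be unsigned 16-bit integers (0..65535)")
  invisible(x)
}

stopifnotU32 <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x >= 2^32) || any(x != floor(x)))
    stop(what, " must be unsigned 32-bit integers (0..2^32-1)")
  invisible(x)
}

# 8-hex-digit rendering of an unsigned 32-bit value held as a double
# (as.hexmode overflows R's signed integers above 2^31)
hex32 <- function(x) sprintf("%04x%04x", as.integer(x %/% 65536),
                             as.integer(x %% 65536))

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
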