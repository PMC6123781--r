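# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# All permutations of a character vector, in lexicographic order of the
# resulting sequences (by element order of `x` as declared).
#' @noRd
permutations <- function(x) {
  n <- length(x)
  if (n == 0L) return(list(character(0)))
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

# FNV-1a 32-bit hash over a character string, returned as 8 hex digits.
# Multiplication is split into 16-bit halves so intermediates stay inside
# the exactly-representable double range.
# Vectorized over a character vector: the per-byte update runs once per
# string *position* with all strings advanced in parallel.
#' @noRd
fnv1a32_hex <- function(s) {
  n <- length(s)
  lens <- nchar(s, type = "bytes")
  maxlen <- max(lens, 0L)
  bm <- matrix(NA_integer_, nrow = n, ncol = maxlen)
  for (i in seq_len(n)) {
    b <- utf8ToInt(s[i])
    if (length(b)) bm[i, seq_along(b)] <- b
  }
  h <- rep(2166136261, n)
  prime <- 16777619
  for (j in seq_len(maxlen)) {
    b <- bm[, j]
    act <- !is.na(b)
    if (!any(act)) next
    ha <- h[act]
    # XOR on doubles < 2^32 via 16-bit halves (bitwXor needs ints < 2^31)
    h_lo <- ha %% 65536
    h_hi <- (ha - h_lo) / 65536
    x_lo <- bitwXor(as.integer(h_lo), b[act]) # bytes < 2^16: hi half unaffected
    ha <- h_hi * 65536 + x_lo
    # multiply mod 2^32, again in halves
    h_lo <- ha %% 65536
    h_hi <- (ha - h_lo) / 65536
    ha <- ((h_hi * prime) %% 65536) * 65536 + h_lo * prime
    h[act] <- ha %% 4294967296
  }
  lo <- h %% 65536
  hi <- (h - lo) / 65536
  sprintf("%04x%04x", as.integer(hi), as.integer(lo))
}

# Run `expr` with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library code has no side effects on simulations.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Greatest common divisor for exact compression ratios.
#' @noRd
gcd <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}
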