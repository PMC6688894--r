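# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invariant <- function(what, ...) {
  stop(sprintf(what, ...), call. = FALSE)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

# Swap quadrants so the zero-frequency bin moves to the centre
# (index floor(n/2)+1 along each dimension), matching the usual
# centred k-space display convention.
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  m[c(seq_len(n1 - s1) + s1, seq_len(s1)),
    c(seq_len(n2 - s2) + s2, seq_len(s2)), drop = FALSE]
}

ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- ceiling(n1 / 2); s2 <- ceiling(n2 / 2)
  m[c(seq_len(n1 - s1) + s1, seq_len(s1)),
    c(seq_len(n2 - s2) + s2, seq_len(s2)), drop = FALSE]
}

# Signed frequency index of each row of a centred k-space of n rows.
centred_freqs <- function(n) seq_len(n) - 1L - floor(n / 2)
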