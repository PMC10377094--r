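#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state so generators are pure functions of
# their seed and never disturb the caller's random stream.
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
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic fan-out of one user seed into per-stage / per-item seeds,
# kept strictly below 2^31 so set.seed() accepts them on 32-bit integers.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 16807
  as.integer(s %% 2147483629L) + 1L
}

# Round half away from zero, the convention used by the published
# percent-scale tables (4 decimals).
round_half_up <- function(x, digits = 4) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
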