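#' Seeded random-number streams
#'
#' Cohort generation must be reproducible *and* order-independent: patient
#' `i` is identical whether generated alone or inside a batch. Each patient
#' therefore gets a private RNG stream whose seed is a deterministic mix of
#' the master seed and the patient index. A stream carries its own
#' `.Random.seed` state, which is swapped into the session only for the
#' duration of a draw, so streams never interfere with each other or with
#' the caller's RNG.
#'
#' @param seed integer seed for the stream.
#' @return an object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  e <- new.env(parent = emptyenv())
  ge <- globalenv()
  old <- get0(".Random.seed", envir = ge, inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = ge, inherits = FALSE)
  if (is.null(old)) {
    rm(".Random.seed", envir = ge)
  } else {
    assign(".Random.seed", old, envir = ge)
  }
  class(e) <- "rng_stream"
  e
}

#' Derive a per-patient stream seed from a master seed
#'
#' Deterministic integer mix of `(master, index)`; all arithmetic stays below
#' 2^53 so the result is exact in doubles, and the returned seed is in
#' `[1, 2^31 - 2]`.
#'
#' @param master master seed (integer).
#' @param index 1-based patient index (or any non-negative stream label).
#' @return integer seed.
#' @export
derive_stream_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1, prime
  a <- as.double(master) %% m
  b <- as.double(index) %% m
  x <- (a * 48271 + b * 69621 + 374761393) %% m
  x <- (x * 16807 + b * 12345 + 1) %% m
  as.integer(x %% (m - 1) + 1)
}

#' Evaluate a draw function under a stream's RNG state
#'
#' @param stream an [rng_stream()].
#' @param fn a zero-argument function performing the draws.
#' @return the value of `fn()`.
#' @export
with_stream <- function(stream, fn) {
  stopifnot(inherits(stream, "rng_stream"))
  ge <- globalenv()
  old <- get0(".Random.seed", envir = ge, inherits = FALSE)
  assign(".Random.seed", stream$state, envir = ge)
  on.exit({
    stream$state <- get(".Random.seed", envir = ge, inherits = FALSE)
    if (is.null(old)) {
      if (exists(".Random.seed", envir = ge, inherits = FALSE)) {
        rm(".Random.seed", envir = ge)
      }
    } else {
      assign(".Random.seed", old, envir = ge)
    }
  })
  fn()
}

#' Draw uniforms from a stream
#' @param stream an [rng_stream()].
#' @param n number of draws.
#' @return numeric vector of `n` uniforms on (0, 1).
#' @export
stream_runif <- function(stream, n = 1L) {
  with_stream(stream, function() stats::runif(n))
}

# Cheap deterministic string hash on [0, mod): used by the scripted mock
# backend to vary phrasings without consuming RNG state.
hash_string <- function(s, mod = 2147483647) {
  h <- 0
  for (cp in utf8ToInt(enc2utf8(s))) {
    h <- (h * 131 + cp) %% mod
  }
  h
}

# Deterministic pseudo-uniform in [0, 1) from a string.
hash_unit <- function(s) {
  hash_string(s) / 2147483647
}
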