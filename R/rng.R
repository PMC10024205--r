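#' Derive a reproducible child seed from a set of integer keys
#'
#' Folds an arbitrary number of integer keys (master seed, cycle index,
#' event-slot index, draw index, ...) into a single seed in
#' `[0, 2^31 - 2]` using a multiplicative-congruential fold.  Within one
#' master seed, distinct `(cycle, slot)` or `(draw)` key tuples map to
#' distinct streams, which is what common-random-number (CRN) pairing of
#' scenarios relies on: the random draw consumed by individual *i* in
#' cycle *t* for event slot *s* depends only on `(master, t, s, i)`, never
#' on scenario parameters.
#'
#' @param ... integer-valued scalars (coerced with `%%` to the modulus).
#' @return A single integer seed suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(42, 3, 1)
derive_seed <- function(...) {
  ks <- as.numeric(c(...))
  stopifnot(length(ks) >= 1L, all(is.finite(ks)))
  m <- 2147483647 # 2^31 - 1 (prime); products stay exact in doubles
  h <- 104729
  for (k in ks) {
    h <- (h * 69069 + (abs(k) %% m) + 1) %% m
  }
  as.integer(h)
}

# Uniform draws for one (cycle, slot) event stream.  Always draws for the
# full population (length n), dead individuals included, so that draw i
# belongs to individual i in every scenario sharing the seed.
crn_uniforms <- function(seed, cycle, slot, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(derive_seed(seed, cycle, slot))
  stats::runif(n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate expr with a locally set seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  expr
}
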