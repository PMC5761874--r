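# Run code under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from a base seed and an index, staying inside the
# 32-bit integer range.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103L + 7919 * as.numeric(index)) %% 2147483647)
}

# logistic-simplex map: two unconstrained reals -> (a, b) with a, b >= 0,
# a + b < 1 (total persistence s = plogis(x1), split r = plogis(x2)).
simplexFromRaw <- function(x) {
  s <- stats::plogis(x[1])
  r <- stats::plogis(x[2])
  c(s * r, s * (1 - r))
}

rawFromSimplex <- function(ab) {
  s <- min(max(sum(ab), 1e-8), 1 - 1e-8)
  r <- min(max(ab[1] / s, 1e-8), 1 - 1e-8)
  c(stats::qlogis(s), stats::qlogis(r))
}
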