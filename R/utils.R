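# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. With seed = NULL the code runs on the
# ambient RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

# Running minimum / maximum over a centred window of `k` points (k odd),
# replicate-padded at the ends. Implemented as pmin/pmax folds over the
# lagged-embedding columns, which is fast enough for full spectra.
run_extreme <- function(x, k, which = c("min", "max")) {
  which <- match.arg(which)
  stopifnot(k >= 1L, k %% 2L == 1L)
  if (k == 1L) return(x)
  h <- (k - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  m <- embed(xp, k)  # rows: windows, columns: lags
  fn <- if (which == "min") pmin else pmax
  do.call(fn, as.data.frame(m))
}

# Morphological opening with a flat structuring element of k points.
morph_open <- function(x, k) {
  run_extreme(run_extreme(x, k, "min"), k, "max")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
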