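# Internal helpers.

# A self-contained RNG stream: draws are reproducible under `seed` and do
# not disturb (or depend on) the caller's global random state.
local_rng <- function(seed) {
  stopifnot(length(seed) == 1, is.finite(seed))
  state <- NULL
  run <- function(f) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    if (is.null(state)) set.seed(as.integer(seed)) else {
      assign(".Random.seed", state, globalenv())
    }
    on.exit({
      state <<- get(".Random.seed", globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, globalenv())
      }
    })
    f()
  }
  list(
    runif = function(n, min = 0, max = 1) {
      run(function() stats::runif(n, min, max))
    },
    rnorm = function(n, mean = 0, sd = 1) {
      run(function() stats::rnorm(n, mean, sd))
    },
    sample_int = function(n, size, replace = FALSE, prob = NULL) {
      run(function() sample.int(n, size, replace = replace, prob = prob))
    },
    with = run
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
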