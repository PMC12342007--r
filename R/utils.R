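# Shared internal helpers.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so package functions never perturb the global stream.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one parent seed (all < 2^31).
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max, n))
}

# format() at full double precision for plain-text export.
full_precision <- function(x) {
  vapply(x, function(v) format(v, digits = 17, scientific = FALSE,
                               trim = TRUE), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
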