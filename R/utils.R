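# internal helpers shared across modules

# stop with a classed condition so callers/tests can distinguish error kinds
stop_ribohet <- function(message, class) {
  rlang::abort(message, class = c(class, "ribohet_error"))
}

# geometric mean that returns 0 when any element is 0 (log-space otherwise)
geom_mean <- function(x) {
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

# deterministic RNG scope: run `code` under a local seed without touching the
# caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

`%||%` <- rlang::`%||%`
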