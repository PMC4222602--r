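# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# Wrap an angle (radians) to (-pi, pi].
circ_wrap <- function(x) atan2(sin(x), cos(x))

# Circular mean of angles in radians.
circ_mean <- function(x) Arg(mean(exp(1i * x)))

# Derive a per-unit RNG seed from a master seed so parallel/streamed work is
# reproducible without consuming the global RNG state between units.
# Constants keep the result a valid 32-bit integer.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %%
               2147483647L)
}

# Run `expr` under a fixed seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

stop_hw <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "hairwave_error")))
}
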