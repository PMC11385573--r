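# Internal helpers shared across modules.

# Classed conditions so callers can distinguish failure modes programmatically.
ps_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "paleoseg_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

ps_assert <- function(cond, class, msg, ...) {
  if (!isTRUE(cond)) ps_error(class, msg, ...)
  invisible(TRUE)
}

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so seeded internals never perturb user-level randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Uniform integer in [lo, hi] drawn from the current RNG stream.
runif_int <- function(n, lo, hi) {
  lo + floor(stats::runif(n) * (hi - lo + 1L))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
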