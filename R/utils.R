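# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so no function leaves hidden global state behind.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Clamp x into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic median split used for both IR-high/low and IRR-high/low
# group assignment: values strictly above the median are "high"; ties at
# the median go to "low".
median_split <- function(x) {
  med <- stats::median(x)
  factor(ifelse(x > med, "high", "low"), levels = c("low", "high"))
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
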