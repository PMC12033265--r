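# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers (and the CLI) can distinguish malformed input
# from violated case invariants.
stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("ystr_parse_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("ystr_validation_error", "error")))
}

stop_cap <- function(...) {
  stop(errorCondition(paste0(...), class = c("ystr_cap_exceeded", "error")))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL means: use (and advance) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != trunc(seed)) {
    stop_validation("seed must be a single integer")
  }
  if (abs(seed) >= 2^31) stop_validation("seed must fit in a 32-bit integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Locale-independent lexicographic order for member ids.
lex_order <- function(x) order(x, method = "radix")
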