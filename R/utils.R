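# Internal helpers shared across modules.

# Evaluate `expr` under a given seed without disturbing the caller's RNG
# stream; with seed = NULL the expression still runs but uses (and advances)
# the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible 31-bit sub-seed from a base seed and a component tag.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
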