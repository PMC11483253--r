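# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. Keeps evaluation seeds from perturbing training streams.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

clip01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)
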