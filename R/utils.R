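# internal helpers shared across modules

# Restore the global RNG state after running `code` under `seed`.
# Keeps bootstrap / fixture generation from disturbing the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit hash of a scenario key, combined with the user seed.
# Every scenario (distribution x n x estimator) gets its own substream so
# results do not depend on the order cells are run in.
cell_seed <- function(seed, ...) {
  key <- paste(..., sep = "|")
  h <- 0
  m <- 2147483647
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  out <- (h + (as.numeric(seed) %% m)) %% m
  if (out == 0) out <- 1
  as.integer(out)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
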