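clamp01 <- function(x) pmin(pmax(x, 0), 1)

# min-max rescale to [0,1]; constant input maps to all zeros
minmax <- function(x) {
  r <- range(x)
  if (!all(is.finite(r))) stop("non-finite values in input", call. = FALSE)
  if (r[2] - r[1] <= 0) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

# derive a 32-bit sub-seed from a master seed and a stream offset
derive_seed <- function(seed, offset) {
  as.integer(((as.numeric(seed) %% 2147483647) * 1009 + offset) %%
               2147483647)
}

# evaluate expr under a temporary RNG state seeded with `seed`;
# seed = NULL uses (and advances) the current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
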