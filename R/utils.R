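# Internal helpers shared across modules.

# Deterministic sub-seed derivation (Lehmer step); keeps every derived seed in
# [1, 2^31 - 2] so set.seed() never sees an overflowing integer.
deriveSeed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(offset)
  as.integer(s %% 2147483646 + 1)
}

# Evaluate `expr` under a local RNG state so callers' streams are untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Cheap content fingerprint for run manifests (no external digest dependency).
stageHash <- function(x) {
  v <- suppressWarnings(as.numeric(unlist(x, use.names = FALSE)))
  v <- v[is.finite(v)]
  if (length(v) == 0) return("empty")
  paste0(length(v), "-", format(sum(v), digits = 15), "-",
         format(sum(v * seq_along(v) %% 97), digits = 15))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
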