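`%||%` <- function(x, y) if (is.null(x)) y else x

# round half away from zero (2.5 -> 3, -2.5 -> -3), unlike base round()
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# deterministic stream of sub-seeds below 2^31, all arithmetic exact in doubles
derive_seed <- function(seed, ...) {
  h <- (abs(as.numeric(seed)) %% 2147483647)
  for (k in c(...)) {
    h <- (h * 48271 + abs(as.numeric(k)) + 1) %% 2147483647
  }
  as.integer(h)
}

# polynomial rolling hash of a character vector, hex string; config digests
text_digest <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647  # exact in doubles
  sprintf("%08x", as.integer(h))
}

# evaluate expr with a local RNG seed, restoring any prior RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
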