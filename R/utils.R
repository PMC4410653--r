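# shared helpers: seeded evaluation without disturbing the caller's RNG
# state, and deterministic sub-seed derivation for shards/streams

local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed from (seed, stream index); stays below 2^31 so it is
# always a valid integer seed
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer(((s * 48271 + as.double(index) * 10007 + 12345) %% 2147483629) + 1)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
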