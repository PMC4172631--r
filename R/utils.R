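# Fan a single user seed out into k independent per-stage seeds. All
# randomness in the package flows through this helper so that one global
# seed reproduces an entire experiment; the stream order is the order in
# which stages request their seed.
derive_seeds <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, k)
}

# Run expr under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

next_pow2 <- function(n) 2L^ceiling(log2(n))

`%||%` <- function(a, b) if (is.null(a)) b else a
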