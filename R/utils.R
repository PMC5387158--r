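# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# Deterministic child seed from a master seed and a stage label.
# Simple 32-bit polynomial string hash; keeps every derived seed in
# [0, 2^31 - 1] so it is a valid R integer seed.
derive_seed <- function(master_seed, label) {
  stopifnot_scalar_number(master_seed, "master_seed")
  h <- as.double(master_seed %% 2147483647)
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a locally-seeded RNG without disturbing the caller's
# RNG state. `seed = NULL` uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Chunk n ranked items into k consecutive groups whose sizes differ by <= 1
# (earlier groups take the remainder). Returns the group id per rank 1..n.
chunk_ranks <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k) + as.integer(seq_len(k) <= n %% k)
  rep(seq_len(k), times = sizes)
}
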