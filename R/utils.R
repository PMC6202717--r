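# internal helpers: argument checking and seed derivation

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dd <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_dd(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    stop_dd(sprintf("`%s` must be > 0 (got %g)", name, x))
  as.numeric(x)
}

# Counter-scheme seed derivation: replicate b of a run seeded with `seed`
# always gets the same stream, so enlarging B extends the bootstrap without
# reshuffling earlier replicates. Kept within [1, 2^31 - 2] for set.seed().
derive_seed <- function(seed, b) {
  s <- (as.numeric(seed) %% 2147483647) + 104729 * as.numeric(b)
  as.integer(s %% 2147483646) + 1L
}

# set.seed that tolerates NULL (leave RNG untouched)
set_seed_maybe <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
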