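# Seed plumbing: every stochastic entry point takes an optional integer seed.
# Evaluation under a seed must not disturb the caller's RNG stream, and child
# seeds for substreams (MC draws, BS resamples, test pairings, per-run seeds)
# are derived deterministically from the master seed.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# k child seeds in [1, 2^31 - 2], deterministic in `seed`; NULL stays NULL
.child_seeds <- function(seed, k) {
  if (is.null(seed)) return(vector("list", k))
  as.list(.with_seed(seed, sample.int(2147483646L, k)))
}

.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
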