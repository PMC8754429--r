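# Internal helpers shared across modules.

# Evaluate `expr` under a deterministic RNG state derived from `seed`,
# restoring the caller's RNG state afterwards so that seeded helpers do not
# perturb the global stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Counter-based substream scheme: one user-supplied seed spawns independent
# substream seeds, so adding a generator does not perturb existing streams.
# Kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(index), index >= 0)
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483587)
}

# Sample median with the midpoint convention for even n (stats::median).
# Wrapped so the convention is named at call sites.
median_midpoint <- function(x) stats::median(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
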