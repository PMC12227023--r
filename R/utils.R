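# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., call. = FALSE) stop(sprintf(fmt, ...), call. = call.)

assert_scalar_num <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be a single non-missing number", name)
  if (finite && !is.finite(x)) stopf("`%s` must be finite", name)
  if (positive && x <= 0) stopf("`%s` must be > 0 (got %g)", name, x)
  invisible(x)
}

# Convert a duration in seconds to a sample count at sampling rate fs.
seconds_to_samples <- function(seconds, fs) as.integer(round(seconds * fs))

# Deterministic child-seed derivation: Knuth multiplicative hash of the
# (master seed, stream index) pair, kept inside the 32-bit integer range so
# set.seed() accepts it on any platform.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 2654435761) %% 2147483647)
}

# Evaluate an expression with a locally-scoped RNG seed, restoring the
# caller's RNG state afterwards so simulation helpers never perturb the
# global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
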