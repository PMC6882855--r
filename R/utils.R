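# Internal helpers shared across modules.

# Run code with a private RNG state seeded from `seed`, restoring the caller's
# stream afterwards. Keeps generators reproducible without clobbering the
# session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive k child seeds from one parent seed (kept below 2^31).
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

check_triple <- function(x, name, positive = TRUE) {
  if (length(x) != 3L || !is.numeric(x) || any(!is.finite(x)))
    stopf("%s must be a numeric triple", name)
  if (positive && any(x <= 0)) stopf("%s must be strictly positive", name)
  invisible(as.numeric(x))
}
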