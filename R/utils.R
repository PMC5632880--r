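# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# global RNG state. All package randomness flows through this.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old)
      assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.assertScalarNum <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  bad_lo <- if (strict_lower) x <= lower else x < lower
  bad_hi <- if (strict_upper) x >= upper else x > upper
  if (bad_lo || bad_hi)
    stop(sprintf("'%s' = %g is outside its allowed range", name, x),
         call. = FALSE)
  invisible(x)
}

.assertCounts <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  if (any(x < 0))
    stop(sprintf("'%s' contains negative counts", name), call. = FALSE)
  if (any(abs(x - round(x)) > 1e-8))
    stop(sprintf("'%s' contains non-integer counts", name), call. = FALSE)
  invisible(x)
}

# Write `lines` (or run `writer(path)`) atomically: temp file in the target
# directory, then rename over the destination.
.atomicWrite <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = ".tmp-", tmpdir = dirname(path))
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  ok <- TRUE
  invisible(path)
}
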