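# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so seeded calls do not perturb global
# reproducibility. `seed = NULL` uses (and advances) the current RNG.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

# Scalar 1-based closed interval check.
checkInterval <- function(start, end, what = "interval") {
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop(sprintf("%s coordinates must be finite", what))
  if (any(end < start))
    stop(sprintf("malformed %s: end < start", what))
  invisible(TRUE)
}

# Closed-interval overlap for parallel vectors.
intervalsOverlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

# Coerce a two-column matrix / data.frame / numeric(2) to c(start, end).
asStartEnd <- function(x) {
  if (is.numeric(x) && length(x) == 2L) return(unname(x))
  stop("expected a numeric vector c(start, end)")
}
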