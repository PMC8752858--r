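# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`; if seed is NULL
# the current RNG stream is used (and advanced) as usual.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer or NULL")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

checkProb <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must be a probability in [0, 1]", what))
  invisible(x)
}

checkCount <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be an integer >= %d", what, min))
  invisible(as.integer(x))
}

# unordered allele pair, smaller first; preserves NA
orderPair <- function(a, b) {
  swap <- !is.na(a) & !is.na(b) & a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  cbind(a, b, deparse.level = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
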