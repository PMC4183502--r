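# Internal numerical helpers and the package-level cache.

# Package-level cache for log-factorial-heavy tables (prefix DP, marginal
# tables, conditional tables).  Caching is transparent: results are identical
# with options(nnindep.cache = FALSE).
.nn_cache <- new.env(parent = emptyenv())

.cache_enabled <- function() isTRUE(getOption("nnindep.cache", TRUE))

.cache_get <- function(key) {
  if (!.cache_enabled()) return(NULL)
  if (exists(key, envir = .nn_cache, inherits = FALSE))
    get(key, envir = .nn_cache, inherits = FALSE)
  else NULL
}

.cache_set <- function(key, value) {
  if (.cache_enabled()) assign(key, value, envir = .nn_cache)
  value
}

#' Clear the internal table cache
#'
#' Drops all cached distribution tables (prefix-count dynamic programs,
#' marginal tables, conditional tables).  Results never depend on the cache;
#' this only frees memory.
#'
#' @return Invisibly, the number of objects dropped.
#' @export
nn_cache_clear <- function() {
  n <- length(ls(.nn_cache))
  rm(list = ls(.nn_cache), envir = .nn_cache)
  invisible(n)
}

# log(sum(exp(x))) of a vector, stable, empty -> -Inf
.logsumexp <- function(x) {
  x <- x[!is.nan(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# elementwise log(exp(a) + exp(b)), stable, handles -Inf
.lse2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  bad <- !is.finite(m)
  out[bad] <- m[bad]
  out
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so package functions do not disturb the user's stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

.is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}
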