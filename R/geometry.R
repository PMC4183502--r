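# Rank transformation, torus Chebyshev metric and nearest-neighbour
# distance profiles: the data model every other component consumes.

#' Rank-transform a numeric vector to a permutation of 0..n-1
#'
#' Replaces values by their zero-based ranks.  Ties are broken uniformly at
#' random under `tie_seed`, because the exact distance distributions assume
#' genuine permutations: deterministic mid-ranks would leave duplicated grid
#' coordinates and break the one-point-per-line model.
#'
#' @param values numeric vector, all finite, length >= 2.
#' @param tie_seed integer seed used only for tie-breaking; identical input
#'   and seed give identical output.
#' @return integer vector, a permutation of `0:(length(values) - 1)`.
#' @examples
#' rank_to_permutation(c(2.5, 1.1, 3.3))
#' @export
rank_to_permutation <- function(values, tie_seed = 1L) {
  if (length(values) < 2L)
    .stopf("need at least 2 values, got %d", length(values))
  bad <- which(!is.finite(values))
  if (length(bad))
    .stopf("non-finite value at index %d", bad[1L])
  r <- .with_seed(tie_seed, rank(values, ties.method = "random"))
  as.integer(r) - 1L
}

#' Paired permutations (the rank-transformed sample)
#'
#' A sample of `n` points `(x[k], y[k])` on the `n` x `n` torus in which each
#' horizontal and each vertical grid line carries exactly one point, i.e.
#' `x` and `y` are permutations of `0:(n-1)` paired by index.
#'
#' @param x,y integer vectors, each a permutation of `0:(n-1)`.
#' @return an object of class `"permutation_pair"` with fields `n`, `x`, `y`.
#' @seealso [as_permutation_pair()] to build one from raw numeric data.
#' @export
permutation_pair <- function(x, y) {
  x <- as.integer(x); y <- as.integer(y)
  n <- length(x)
  if (length(y) != n) .stopf("x and y must have equal length")
  if (n < 2L) .stopf("need n >= 2")
  if (!identical(sort(x), 0:(n - 1L)))
    .stopf("x is not a permutation of 0..n-1")
  if (!identical(sort(y), 0:(n - 1L)))
    .stopf("y is not a permutation of 0..n-1")
  structure(list(n = n, x = x, y = y), class = "permutation_pair")
}

#' @export
print.permutation_pair <- function(x, ...) {
  cat(sprintf("permutation pair on the %d x %d torus\n", x$n, x$n))
  invisible(x)
}

#' Rank-transform raw paired data to a permutation pair
#'
#' @param x,y numeric vectors of equal length (finite values).
#' @param tie_seed seed for random tie-breaking, see [rank_to_permutation()].
#' @return a [permutation_pair()].
#' @export
as_permutation_pair <- function(x, y, tie_seed = 1L) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  permutation_pair(rank_to_permutation(x, tie_seed),
                   rank_to_permutation(y, tie_seed + 1L))
}

#' Draw a permutation pair uniformly at random
#'
#' Both coordinate permutations are drawn independently and uniformly from
#' the symmetric group; this is the null model of independence.
#'
#' @param n sample size.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (and advanced).
#' @return a [permutation_pair()].
#' @export
random_permutation_pair <- function(n, seed = NULL) {
  draw <- function() permutation_pair(sample.int(n) - 1L, sample.int(n) - 1L)
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Torus Chebyshev distance
#'
#' Distance between points `p = (a, b)` and `q = (c, e)` on the `n` x `n`
#' torus under the maximum metric with per-axis wraparound:
#' `max(delta(a, c), delta(b, e))` with `delta(u, v) = min(|u - v|, n - |u - v|)`.
#'
#' @param p,q length-2 integer vectors with coordinates in `0:(n-1)`.
#' @param n torus size.
#' @return integer distance in `0:max_distance(n)`.
#' @examples
#' torus_chebyshev_distance(c(0, 0), c(3, 5), 8) # 3
#' torus_chebyshev_distance(c(0, 0), c(4, 0), 5) # 1 (wraparound)
#' @export
torus_chebyshev_distance <- function(p, q, n) {
  if (length(p) != 2L || length(q) != 2L) .stopf("points must have 2 coordinates")
  co <- c(p, q)
  if (any(co < 0 | co > n - 1 | co != round(co)))
    .stopf("coordinates must be integers in 0..n-1")
  d <- abs(p - q)
  as.integer(max(pmin(d, n - d)))
}

#' Largest attainable torus distance
#'
#' The support of the metric on the `n` x `n` torus is `0:floor(n/2)`.
#'
#' @param n torus size, `n >= 2`.
#' @return `floor(n / 2)`.
#' @export
max_distance <- function(n) {
  if (!.is_count(n, 2L)) .stopf("n must be an integer >= 2")
  as.integer(n) %/% 2L
}

# all pairwise torus (or plane) Chebyshev distances of a permutation pair;
# diagonal set to NA
.distance_matrix <- function(pp, geometry = c("torus", "plane")) {
  geometry <- match.arg(geometry)
  n <- pp$n
  dx <- abs(outer(pp$x, pp$x, "-"))
  dy <- abs(outer(pp$y, pp$y, "-"))
  if (geometry == "torus") {
    dx <- pmin(dx, n - dx)
    dy <- pmin(dy, n - dy)
  }
  D <- pmax(dx, dy)
  diag(D) <- NA_integer_
  D
}

#' Nearest-neighbour distance profile
#'
#' For every sample point, the nondecreasing sequence of Chebyshev distances
#' to its 1st..`i_max`-th nearest neighbours.  Only distances are reported;
#' neighbour identities are not part of the contract.  Under the torus
#' geometry each row lies in `1:max_distance(n)` and no value repeats more
#' than four times in a row (at most four points sit at any exact torus
#' distance from a given point).
#'
#' @param pp a [permutation_pair()].
#' @param i_max number of neighbours per point, `1 <= i_max <= n - 1`.
#' @param geometry `"torus"` (the model under which the exact distributions
#'   hold; default) or `"plane"` (no wraparound, for geometry comparisons).
#' @return an object of class `"nn_profile"`: a list with `n`, `i_max`,
#'   `geometry`, and `d`, an `n` x `i_max` integer matrix with `d[k, i]` the
#'   distance of the `i`-th nearest neighbour of point `k`.
#' @export
nn_distance_profile <- function(pp, i_max = NULL,
                                geometry = c("torus", "plane")) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(pp, "permutation_pair"))
  n <- pp$n
  if (is.null(i_max)) i_max <- n - 1L
  if (!.is_count(i_max, 1L) || i_max > n - 1L)
    .stopf("i_max must be an integer in 1..n-1 (n = %d)", n)
  D <- .distance_matrix(pp, geometry)
  d <- t(apply(D, 1L, function(z) sort.int(z[!is.na(z)],
                                           method = "quick")[seq_len(i_max)]))
  if (i_max == 1L) d <- matrix(as.integer(d), ncol = 1L)
  storage.mode(d) <- "integer"
  structure(list(n = n, i_max = as.integer(i_max), geometry = geometry, d = d),
            class = "nn_profile")
}

#' @export
print.nn_profile <- function(x, ...) {
  cat(sprintf("nearest-neighbour profile: n = %d, i_max = %d, %s geometry\n",
              x$n, x$i_max, x$geometry))
  invisible(x)
}
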