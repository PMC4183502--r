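# Independent validators of the closed-form counting: exhaustive enumeration
# of all (n-1)! configurations (exact integer counts) and Monte-Carlo
# frequency estimation.

# all permutations of 1..k as a k! x k integer matrix
.all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 0L
  for (pos in seq_len(k)) {
    blk <- nrow(sub)
    idx <- row + seq_len(blk)
    if (pos > 1L) out[idx, seq_len(pos - 1L)] <- sub[, seq_len(pos - 1L)]
    out[idx, pos] <- k
    if (pos < k) out[idx, pos + seq_len(k - pos)] <- sub[, (pos:(k - 1L))]
    row <- row + blk
  }
  out
}

#' Exact joint law of all neighbour distances by exhaustive enumeration
#'
#' Enumerates all `(n - 1)!` configurations of the non-reference points
#' (reference fixed at the origin, i.e. all bijections between the remaining
#' columns and rows) and tallies the sorted distance sequence of each.  The
#' counts are exact integers; this is the independent oracle against which
#' the closed-form counting is validated.
#'
#' @param n torus size, `3 <= n <= 9` (enumeration of `(n - 1)!`
#'   configurations; use [monte_carlo_frequency()] beyond that).
#' @return a list of class `"nn_enumeration"` with `n`, `total` =
#'   `(n - 1)!`, `sequences` (unique sorted distance sequences, one per
#'   row), `count` (configurations per sequence) and `prob`
#'   (`count / total`), plus `distances`, the full per-configuration sorted
#'   distance matrix.
#' @export
brute_force_distribution <- function(n) {
  if (!.is_count(n, 3L)) .stopf("n must be an integer >= 3")
  if (n > 9L)
    .stopf(paste("n = %d would enumerate %s configurations;",
                 "use monte_carlo_frequency() for large n"),
           n, format(factorial(n - 1), big.mark = ","))
  k <- n - 1L
  perms <- .all_permutations(k)
  ax <- pmin(seq_len(k), n - seq_len(k)) # axis distance of coordinate u
  D <- pmax(matrix(ax, nrow(perms), k, byrow = TRUE),
            matrix(ax[perms], nrow(perms), k))
  D <- t(apply(D, 1L, sort.int, method = "quick"))
  keys <- apply(D, 1L, paste, collapse = ",")
  tab <- table(keys)
  seqs <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
  structure(list(n = n, total = nrow(perms), sequences = seqs,
                 count = as.numeric(tab), prob = as.numeric(tab) / nrow(perms),
                 distances = D),
            class = "nn_enumeration")
}

#' @export
print.nn_enumeration <- function(x, ...) {
  cat(sprintf("exhaustive law of (D_1..D_%d) at n = %d: %d sequences over %d configurations\n",
              x$n - 1L, x$n, nrow(x$sequences), x$total))
  invisible(x)
}

#' Monte-Carlo frequencies of the i-th neighbour distance
#'
#' Empirical distribution of `D_i` (distance of the `i`-th nearest neighbour
#' of the reference point) over `reps` independent uniformly random
#' configurations; reproducible under `seed`.
#'
#' @param n torus size.
#' @param i neighbour index, `1 <= i <= n - 1`.
#' @param reps number of random configurations.
#' @param seed integer seed.
#' @return named numeric vector of frequencies over distances
#'   `1:max_distance(n)`, summing to 1.
#' @export
monte_carlo_frequency <- function(n, i, reps, seed = 1L) {
  if (!.is_count(n, 3L)) .stopf("n must be an integer >= 3")
  if (!.is_count(i, 1L) || i > n - 1L) .stopf("need 1 <= i <= n - 1")
  if (!.is_count(reps, 1L)) .stopf("reps must be a positive integer")
  k <- n - 1L
  M <- n %/% 2L
  ax <- pmin(seq_len(k), n - seq_len(k))
  .with_seed(seed, {
    # ranks within rows of a reps x k uniform matrix = random bijections
    u <- stats::runif(reps * k)
    rowid <- rep(seq_len(reps), times = k)
    rk <- integer(reps * k)
    rk[order(rowid, u)] <- rep(seq_len(k), times = reps)
    sig <- matrix(rk, reps, k)
    D <- pmax(matrix(ax, reps, k, byrow = TRUE), matrix(ax[sig], reps, k))
    # D_i per row via cumulative shell counts (avoids per-row sorting)
    cum <- matrix(0L, reps, M)
    acc <- integer(reps)
    for (d in 1:M) {
      acc <- acc + rowSums(D == d)
      cum[, d] <- acc
    }
    di <- max.col(cum >= i, ties.method = "first")
    stats::setNames(tabulate(di, nbins = M) / reps, seq_len(M))
  })
}
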