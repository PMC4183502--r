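# Exact joint, conditional and marginal distributions of the i-th
# nearest-neighbour torus-Chebyshev distances of a uniformly random
# permutation pair, by closed-form counting of admissible configurations.
#
# Model.  The reference point is fixed at the origin (the metric is
# translation invariant); the remaining n-1 points form a uniformly random
# bijection between the remaining n-1 columns and rows.  A coordinate
# u in 1..n-1 has axis distance delta(u) = min(u, n-u) in 1..floor(n/2);
# a point's distance to the origin is the larger of its two axis distances.
#
# Shell structure.  For d < n/2 exactly two columns (u = d, n-d) and two
# rows are at axis distance d; for even n the antipodal shell d = n/2 has a
# single column and row (the degenerate "pair of lines" case).  Write
# m(d) in {1, 2} for the per-axis line count and K(d) for the number of
# columns (equivalently rows) at axis distance <= d.  A configuration whose
# points are counted shell by shell leaves, after shell d, an equal number
# F = K(d) - (points placed) of "open" columns and rows at axis distance
# <= d; every open column/row must eventually pair with a row/column at
# larger axis distance, otherwise an extra point would appear within
# distance d.
#
# Placing e points exactly at distance d (the border region R) with F open
# interior lines per axis decomposes by point type:
#   corner    : new column x new row   (both axis distances equal d),
#   column-edge: new column x open interior row,
#   row-edge  : open interior column x new row,
# with at most m(d) new columns and m(d) new rows available, which caps e at
# 2*m(d) -- at most 4 points on any exact-distance border.  Summing over the
# type split (c, p, q) gives the border count W(e; F, m) implemented in
# `.log_region_count()` and surfaced as `region_r_combinations()`.
#
# Points strictly beyond distance d pair F open columns with new rows and F
# open rows with new columns injectively, then biject the remainder:
# O(F, N) = (N!/(N-F)!)^2 * (N-F)! completions with N new lines per axis.
#
# All arithmetic is in log space (lgamma/lchoose); the enumeration oracle
# (`brute_force_distribution()`, exact integer counts) arbitrates.

# number of columns (= rows) at axis distance <= d
.K <- function(n, d) {
  ifelse(d <= 0L, 0L, 2L * d - as.integer(n %% 2L == 0L & d == n %/% 2L))
}

# grid lines per axis exactly at axis distance d (1 iff even n and d = n/2)
.shell_m <- function(n, d) {
  ifelse(n %% 2L == 0L & d == n %/% 2L, 1L, 2L)
}

# log falling factorial F * (F-1) * ... * (F-p+1), -Inf where F < p
.log_ff <- function(F, p) {
  out <- rep(-Inf, length(F))
  ok <- F >= p
  if (p == 0L) out[ok] <- 0
  else out[ok] <- lgamma(F[ok] + 1) - lgamma(F[ok] - p + 1)
  out
}

# log W(k; F, m): admissible placements of k points on the distance-d border
# given F open interior lines per axis and m new lines per axis.
# Vectorized over F.
.log_region_count <- function(k, F, m) {
  out <- rep(-Inf, length(F))
  if (k < 0L || k > 2L * m) { out[F >= 0] <- -Inf; return(out) }
  if (k == 0L) { out[F >= 0] <- 0; return(out) }
  for (cc in 0:min(k, m)) {
    pmaxi <- min(k - cc, m - cc)
    for (p in 0:pmaxi) {
      q <- k - cc - p
      if (q > m - cc) next
      base <- 2 * lchoose(m, cc) + lfactorial(cc) +
        lchoose(m - cc, p) + lchoose(m - cc, q)
      out <- .lse2(out, base + .log_ff(F, p) + .log_ff(F, q))
    }
  }
  out[F < 0] <- -Inf
  out
}

# log O(Fp, Nnew): completions placing all remaining points strictly outside
# the current shell.  Vectorized over Fp (and, if supplied as a vector
# of matching length, over Nnew).
.log_outside <- function(Fp, Nnew) {
  out <- rep(-Inf, length(Fp))
  if (length(Nnew) == 1L) Nnew <- rep(Nnew, length(Fp))
  ok <- Fp >= 0 & Fp <= Nnew
  out[ok] <- 2 * lfactorial(Nnew[ok]) - lfactorial(Nnew[ok] - Fp[ok])
  out
}

# log sum over e >= need of W(e; F, m(d)) * O(F + m - e, Nnew(d)):
# completions whose shell-d occupancy is at least `need`, rest outside.
# Vectorized over parallel vectors ds / Fs.
.log_tail_vec <- function(n, ds, Fs, need) {
  out <- rep(-Inf, length(ds))
  m_vec <- .shell_m(n, ds)
  Nnew <- (n - 1L) - .K(n, ds)
  for (m in unique(m_vec)) {
    idx <- which(m_vec == m)
    emax <- 2L * m
    if (need > emax) next
    acc <- rep(-Inf, length(idx))
    for (e in need:emax) {
      acc <- .lse2(acc, .log_region_count(e, Fs[idx], m) +
                     .log_outside(Fs[idx] + m - e, Nnew[idx]))
    }
    out[idx] <- acc
  }
  out[Fs < 0] <- -Inf
  out
}

.log_tail <- function(n, d, F, need) .log_tail_vec(n, d, F, need)[1L]

# cached per (n, i): log count of completions with exactly i - 1 points
# strictly inside the distance-d square and at least one point at distance
# exactly d, for every d (the d > v factor of every conditional table).
.log_tail_next <- function(n, i) {
  key <- sprintf("T1:%d:%d", n, i)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  M <- n %/% 2L
  ds <- 1:M
  .cache_set(key, .log_tail_vec(n, ds, .K(n, ds - 1L) - (i - 1L), 1L))
}

# Dynamic program over shells: logA[d + 1, s + 1] is the log count of ways
# to place exactly s points within distance d (any split over shells 1..d),
# with the remaining points unplaced.  Cached per n.
.logA_dp <- function(n) {
  key <- sprintf("A:%d", n)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  M <- n %/% 2L
  A <- matrix(-Inf, M + 1L, n)
  A[1L, 1L] <- 0
  if (M >= 1L) for (d in 1:M) {
    m <- .shell_m(n, d)
    Kp <- .K(n, d - 1L)
    prev <- A[d, ]
    cur <- prev # k = 0 contribution (open lines stay open)
    for (k in 1:(2L * m)) {
      if (k > n - 1L) break
      s_to <- k:(n - 1L)
      s_from <- s_to - k
      w <- .log_region_count(k, Kp - s_from, m)
      cur[s_to + 1L] <- .lse2(cur[s_to + 1L], prev[s_from + 1L] + w)
    }
    A[d + 1L, ] <- cur
  }
  .cache_set(key, A)
}

#' Border-region placement counts
#'
#' Number of admissible placements of `e` points exactly at torus distance
#' `d` from the reference point, given that `s` points already sit strictly
#' inside the distance-`d` square.  Placements must respect the
#' one-point-per-row/column constraint; at most 4 points fit on any border
#' (at most 2 on the degenerate antipodal border of an even torus, where the
#' border collapses to one horizontal and one vertical line).
#'
#' @param e number of border points (`e > 4` is inadmissible and counts 0).
#' @param s number of points strictly inside the distance-`d` square.
#' @param d target distance, in `1:max_distance(n)`.
#' @param n torus size.
#' @return the integer count (0 for inadmissible `(e, s)`).
#' @export
region_r_combinations <- function(e, s, d, n) {
  if (!.is_count(n, 2L) || !.is_count(d, 1L) || d > n %/% 2L)
    .stopf("need integer n >= 2 and d in 1..floor(n/2)")
  if (!.is_count(e, 0L) || !.is_count(s, 0L)) .stopf("e and s must be counts")
  if (s + e > n - 1L) return(0)
  F <- .K(n, d - 1L) - s
  round(exp(.log_region_count(as.integer(e), F, .shell_m(n, d))[1L]))
}

# ---- joint / survival / conditional / marginal laws ------------------------

.log_count_admissible <- function(prefix, n) {
  M <- n %/% 2L
  i <- length(prefix)
  if (i < 1L || i > n - 1L) return(-Inf)
  if (any(prefix != round(prefix)) || any(prefix < 1) || any(prefix > M))
    return(-Inf)
  if (is.unsorted(prefix)) return(-Inf)
  k <- tabulate(as.integer(prefix), nbins = M)
  v <- as.integer(prefix[i])
  acc <- 0
  s <- 0L
  if (v > 1L) for (d in 1:(v - 1L)) {
    acc <- acc + .log_region_count(k[d], .K(n, d - 1L) - s, .shell_m(n, d))[1L]
    s <- s + k[d]
    if (!is.finite(acc)) return(-Inf)
  }
  acc + .log_tail(n, v, .K(n, v - 1L) - s, k[v])
}

#' Count configurations realizing a nearest-neighbour distance prefix
#'
#' Number of placements of the `n - 1` non-reference points (reference fixed
#' at the origin) whose sorted distance sequence starts exactly with
#' `prefix`.  Inadmissible prefixes (decreasing, out of range, or with more
#' equal consecutive entries than the border can hold) count 0.
#'
#' @param prefix nondecreasing integer vector of distances.
#' @param n torus size.
#' @return the configuration count as a double (exact for counts below
#'   2^53; use [prob_joint()] for large `n`, which stays in log space).
#' @examples
#' count_admissible(1, 4)      # 6: every configuration has a 1-neighbour
#' count_admissible(c(1, 1), 4) # 2: the two diagonal configurations
#' @export
count_admissible <- function(prefix, n) {
  if (!.is_count(n, 2L)) .stopf("n must be an integer >= 2")
  exp(.log_count_admissible(prefix, n))
}

#' Joint probability of a nearest-neighbour distance prefix
#'
#' `P(D_1 = prefix[1], ..., D_i = prefix[i])` for the reference point of a
#' uniformly random permutation pair: [count_admissible()] divided by
#' `(n - 1)!`, computed in log space.
#'
#' @inheritParams count_admissible
#' @return a probability.
#' @export
prob_joint <- function(prefix, n) {
  if (!.is_count(n, 2L)) .stopf("n must be an integer >= 2")
  exp(.log_count_admissible(prefix, n) - lfactorial(n - 1L))
}

#' Exact CDF of the i-th nearest-neighbour distance
#'
#' `P(D_i <= d)`: the probability that at least `i` points lie within torus
#' distance `d` of the reference point, assembled from the configuration
#' counts (points inside the distance-`d` square, border occupancies, all
#' remaining points strictly outside).
#'
#' @param d distance, `0 <= d <= max_distance(n)`.
#' @param i neighbour index, `1 <= i <= n - 1`.
#' @param n torus size.
#' @return a probability; equals 1 at `d = max_distance(n)`.
#' @export
prob_survival <- function(d, i, n) {
  if (!.is_count(n, 2L) || !.is_count(i, 1L) || i > n - 1L)
    .stopf("need 1 <= i <= n - 1")
  if (!.is_count(d, 0L) || d > n %/% 2L) .stopf("d out of range")
  if (d == 0L) return(0)
  A <- .logA_dp(n)
  Nnew <- (n - 1L) - .K(n, d)
  s <- i:(n - 1L)
  vals <- A[d + 1L, s + 1L] + .log_outside(.K(n, d) - s, Nnew)
  exp(.logsumexp(vals) - lfactorial(n - 1L))
}

.log_marginal_table <- function(n) {
  key <- sprintf("M:%d", n)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  M <- n %/% 2L
  A <- .logA_dp(n)
  logP <- matrix(-Inf, n - 1L, M)
  for (d in 1:M) {
    m <- .shell_m(n, d)
    Kp <- .K(n, d - 1L)
    Kd <- .K(n, d)
    Nnew <- (n - 1L) - Kd
    s <- 0:(n - 2L)
    Aprev <- A[d, s + 1L]
    for (k in 1:(2L * m)) {
      val <- Aprev + .log_region_count(k, Kp - s, m) +
        .log_outside(Kd - s - k, Nnew)
      for (j in 1:k) {
        ii <- s + j
        keep <- which(ii <= n - 1L & is.finite(val))
        if (!length(keep)) next
        idx <- cbind(ii[keep], d)
        logP[idx] <- .lse2(logP[idx], val[keep])
      }
    }
  }
  .cache_set(key, logP - lfactorial(n - 1L))
}

#' Marginal distribution table of all neighbour distances
#'
#' @param n torus size.
#' @return an `(n - 1) x max_distance(n)` matrix; entry `[i, d]` is
#'   `P(D_i = d)`.  Rows sum to 1.
#' @export
marginal_table <- function(n) {
  if (!.is_count(n, 2L)) .stopf("n must be an integer >= 2")
  p <- exp(.log_marginal_table(n))
  dimnames(p) <- list(i = seq_len(n - 1L), d = seq_len(n %/% 2L))
  p
}

#' Marginal probability of the i-th neighbour distance
#'
#' `P(D_i = d)`, either summed over joint prefixes shell by shell
#' (`method = "shell"`) or as a difference of the exact CDF
#' (`method = "survival"`).  The two routes agree to numerical precision.
#'
#' @param i neighbour index.
#' @param d distance.
#' @param n torus size.
#' @param method computation route.
#' @return a probability.
#' @export
prob_marginal <- function(i, d, n, method = c("shell", "survival")) {
  method <- match.arg(method)
  if (!.is_count(i, 1L) || i > n - 1L) .stopf("need 1 <= i <= n - 1")
  if (!.is_count(d, 1L) || d > n %/% 2L) .stopf("d out of range")
  if (method == "shell") exp(.log_marginal_table(n)[i, d])
  else prob_survival(d, i, n) - prob_survival(d - 1L, i, n)
}

#' Exact conditional distribution of the next neighbour distance
#'
#' Distribution of `D_i` given an observed distance history.  The sequence
#' of neighbour distances is a Markov chain of order 4 (a border holds at
#' most 4 points, so the last value and its trailing run length -- capped at
#' 4 -- summarize the whole history); accordingly only the last
#' `min(4, i - 1)` entries of `history` are used, and at least that many
#' must be supplied.  For `i = 1` (empty history) the marginal of `D_1` is
#' returned.
#'
#' @param n torus size.
#' @param i neighbour index of the next distance, `1 <= i <= n - 1`.
#' @param history nondecreasing integer distances `(d_1, ..., d_{i-1})` or
#'   at least their last `min(4, i - 1)` entries.
#' @return a list of class `"nn_conditional"` with `d` (support), `p`
#'   (probabilities, summing to 1), `cdf`, and the conditioning summary
#'   `v` (last value) and `r` (trailing run length).
#' @export
conditional_table <- function(n, i, history = integer(0)) {
  if (!.is_count(n, 3L)) .stopf("n must be an integer >= 3")
  if (!.is_count(i, 1L) || i > n - 1L) .stopf("need 1 <= i <= n - 1")
  M <- n %/% 2L
  L <- min(4L, i - 1L)
  if (L == 0L) {
    p <- exp(.log_marginal_table(n)[1L, ])
    return(structure(list(n = n, i = 1L, v = 0L, r = 0L, d = 1:M,
                          p = p, cdf = cumsum(p)),
                     class = "nn_conditional"))
  }
  if (length(history) < L)
    .stopf("history must contain at least min(4, i - 1) = %d entries", L)
  h <- as.integer(utils::tail(history, L))
  if (any(h < 1L) || any(h > M) || is.unsorted(h))
    .stopf("history must be nondecreasing distances in 1..%d", M)
  v <- h[L]
  r <- 1L
  while (r < L && h[L - r] == v) r <- r + 1L
  .conditional_vr(n, i, v, r)
}

# conditional law of D_i given that the history ends with a maximal run of
# r values equal to v (so exactly i - 1 - r points lie strictly inside the
# distance-v square).  Cached by (n, i, v, r).
.conditional_vr <- function(n, i, v, r) {
  key <- sprintf("C:%d:%d:%d:%d", n, i, v, r)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  M <- n %/% 2L
  s <- i - 1L - r
  F <- .K(n, v - 1L) - s
  A <- .logA_dp(n)
  denom <- if (s < 0L || F < 0L) -Inf
  else A[v, s + 1L] + .log_tail(n, v, F, r)
  if (!is.finite(denom))
    .stopf("conditioning history has probability zero (n=%d, i=%d, v=%d, r=%d)",
           n, i, v, r)
  denom <- .log_tail(n, v, F, r)  # the inside-count factor cancels
  logp <- rep(-Inf, M - v + 1L)
  logp[1L] <- .log_tail(n, v, F, r + 1L) - denom
  if (v < M) {
    base <- .log_region_count(r, F, .shell_m(n, v))[1L] - denom
    logp[2:(M - v + 1L)] <- base + .log_tail_next(n, i)[(v + 1L):M]
  }
  p <- exp(logp)
  .cache_set(key, structure(list(n = n, i = as.integer(i), v = as.integer(v),
                                 r = as.integer(r), d = v:M, p = p,
                                 cdf = cumsum(p)),
                            class = "nn_conditional"))
}

#' @export
print.nn_conditional <- function(x, ...) {
  if (x$i == 1L)
    cat(sprintf("marginal law of D_1 (n = %d)\n", x$n))
  else
    cat(sprintf(
      "conditional law of D_%d given trailing run of %d at distance %d (n = %d)\n",
      x$i, x$r, x$v, x$n))
  print(stats::setNames(x$p, x$d))
  invisible(x)
}

#' Conditional probability from the full joint law
#'
#' `P(D_{i+1} = d_next | D_1..D_i = history)` computed as the ratio of two
#' joint prefix probabilities.  This is the slow full-history route kept as
#' a cross-check of [conditional_table()], which conditions on the last
#' `min(4, length(history))` entries only (the chain has Markov order 4, so
#' the two agree).
#'
#' @param d_next candidate next distance.
#' @param history nondecreasing distance history with positive probability.
#' @param n torus size.
#' @return a probability.
#' @export
prob_conditional <- function(d_next, history, n) {
  ld <- .log_count_admissible(history, n)
  if (!is.finite(ld))
    .stopf("conditioning history has probability zero")
  exp(.log_count_admissible(c(history, d_next), n) - ld)
}

# ---- entropy guidance ------------------------------------------------------

#' Shannon entropy of a discrete distribution
#'
#' Natural-log entropy `-sum(p * log(p))` with the convention
#' `0 * log(0) = 0`.  Accepts a bare probability vector or an
#' `"nn_conditional"` table.
#'
#' @param dist probability vector (or conditional table object).
#' @return entropy in nats, `>= 0`.
#' @export
entropy <- function(dist) {
  p <- if (inherits(dist, "nn_conditional")) dist$p else as.numeric(dist)
  if (any(p < -1e-12)) .stopf("negative probabilities")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Entropy-guided default number of neighbours
#'
#' The marginal entropies `H(D_i)` shrink with `i` as the distributions
#' narrow, but rise again towards `i = n - 1` where the maximal-distance
#' bound constrains the sequence.  Neighbours beyond that turning point
#' carry little usable information, so the default statistic depth is the
#' first local entropy minimum: the first `i`, scanning from the peak of
#' the entropy sequence onward, whose successor entropy is strictly larger.
#' (The sequence can rise marginally from `i = 1` to its early peak, which
#' is why the scan starts at the peak; an absolute tolerance of 1e-9 guards
#' against floating-point wiggle.)  Callers may override the value.
#'
#' @param n sample size, `n >= 4`.
#' @return an integer in `1:(n - 1)`.
#' @examples
#' default_i_max(50) # 25: entropy decreases up to there, then rises
#' @export
default_i_max <- function(n) {
  if (!.is_count(n, 4L)) .stopf("n must be an integer >= 4")
  H <- apply(exp(.log_marginal_table(n)), 1L, entropy)
  up <- which(diff(H) > 1e-9)
  up <- up[up >= which.max(H)]
  if (length(up)) up[1L] else n - 1L
}
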