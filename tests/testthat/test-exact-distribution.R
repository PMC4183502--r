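# The closed-form counting of admissible configurations against its
# independent oracles, and the derived joint / conditional / marginal laws.

test_that("border counts match direct enumeration of placements", {
  # regular border (two grid lines per axis): n = 20, d = 3 gives
  # K(d - 1) = 4 interior lines, so s = 4 - F points inside
  for (F in 0:3) for (e in 0:5) {
    expect_equal(region_r_combinations(e, s = 4L - F, d = 3L, n = 20L),
                 enumerate_border_placements(e, F, m = 2L),
                 info = sprintf("regular border e=%d F=%d", e, F))
  }
  # degenerate antipodal border of an even torus (one line per axis):
  # n = 8, d = 4 has K(3) = 6 interior lines
  for (F in 0:3) for (e in 0:3) {
    expect_equal(region_r_combinations(e, s = 6L - F, d = 4L, n = 8L),
                 enumerate_border_placements(e, F, m = 1L),
                 info = sprintf("degenerate border e=%d F=%d", e, F))
  }
  # no interior points at d = 1 (the n = 6 base case)
  for (e in 0:4)
    expect_equal(region_r_combinations(e, s = 0L, d = 1L, n = 6L),
                 enumerate_border_placements(e, F = 0L, m = 2L))
  # more than 4 points never fit on a border
  expect_identical(region_r_combinations(5L, 0L, 2L, 12L), 0)
})

test_that("count_admissible reproduces the enumerated counts at n = 4", {
  expect_equal(count_admissible(1, 4), 6)
  expect_equal(count_admissible(c(1, 1), 4), 2)
  expect_equal(count_admissible(c(1, 2), 4), 4)
  expect_equal(count_admissible(c(1, 1, 1, 1, 1), 10), 0) # run of 5
  expect_equal(count_admissible(c(2, 1), 6), 0)           # decreasing
})

test_that("joint prefix probabilities equal exhaustive enumeration for n = 3..6", {
  for (n in 3:6) {
    oracle <- brute_force_distribution(n)
    for (len in seq_len(n - 1)) {
      prefixes <- unique(oracle$distances[, seq_len(len), drop = FALSE])
      for (r in seq_len(nrow(prefixes))) {
        p <- prefixes[r, ]
        expect_equal(prob_joint(p, n), oracle_prefix_prob(oracle, p),
                     tolerance = 1e-12,
                     info = sprintf("n=%d prefix %s", n, paste(p, collapse = ",")))
      }
    }
    # full-length prefixes exhaust the probability space
    full <- oracle$sequences
    tot <- sum(apply(full, 1, prob_joint, n = n))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("the exact CDF matches cumulated marginals and saturates at floor(n/2)", {
  expect_equal(prob_survival(1, 1, 4), 1)
  for (n in c(6, 9)) {
    M <- n %/% 2
    tab <- marginal_table(n)
    for (i in seq_len(n - 1)) {
      expect_equal(prob_survival(M, i, n), 1, tolerance = 1e-12)
      cdf <- vapply(1:M, prob_survival, numeric(1), i = i, n = n)
      expect_equal(cdf, cumsum(tab[i, ]), tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("marginals match enumeration and both routes agree", {
  expect_equal(prob_marginal(2, 1, 4), 1 / 3)
  expect_equal(prob_marginal(2, 2, 4), 2 / 3)
  expect_equal(prob_marginal(3, 2, 4), 1)
  expect_equal(prob_marginal(1, 1, 3), 1)
  oracle <- brute_force_distribution(6)
  tab <- marginal_table(6)
  for (i in 1:5)
    expect_equal(tab[i, ], tabulate(oracle$distances[, i], nbins = 3) /
                   oracle$total, tolerance = 1e-12, ignore_attr = TRUE)
  for (n in c(7, 21, 50)) {
    tab <- marginal_table(n)
    expect_equal(rowSums(tab), rep(1, n - 1), tolerance = 1e-10,
                 ignore_attr = TRUE)
    shell <- vapply(seq_len(n %/% 2), prob_marginal, numeric(1),
                    i = 3, n = n, method = "shell")
    surv <- vapply(seq_len(n %/% 2), prob_marginal, numeric(1),
                   i = 3, n = n, method = "survival")
    expect_equal(shell, surv, tolerance = 1e-10)
  }
})

test_that("conditional laws obey the chain rule and match the full-history route", {
  expect_equal(prob_conditional(2, 1, 4), 2 / 3)
  ct <- conditional_table(4, 2, history = 1)
  expect_equal(ct$p, c(1 / 3, 2 / 3), tolerance = 1e-12)
  oracle <- brute_force_distribution(7)
  for (len in 1:5) {
    prefixes <- unique(oracle$distances[, seq_len(len), drop = FALSE])
    for (r in seq_len(nrow(prefixes))) {
      h <- prefixes[r, ]
      truth <- oracle_conditional(oracle, h)
      ct <- conditional_table(7, len + 1, h)
      mine <- numeric(3); mine[ct$d] <- ct$p
      expect_equal(mine, truth, tolerance = 1e-12,
                   info = paste("history", paste(h, collapse = ",")))
      # chain rule: joint = product of conditionals
      joint <- prob_joint(c(h, ct$d[1]), 7)
      expect_equal(joint, prob_joint(h, 7) * ct$p[1], tolerance = 1e-12)
      # ratio-of-joints route agrees with the last-4 Markov route
      for (d in ct$d)
        expect_equal(prob_conditional(d, h, 7), ct$p[match(d, ct$d)],
                     tolerance = 1e-12)
    }
  }
  expect_error(conditional_table(8, 3, history = c(4, 4)), "probability zero")
  expect_error(prob_conditional(2, c(1, 1, 1, 1, 1), 12), "probability zero")
})

test_that("conditional tables are proper distributions with monotone support", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(c(10, 17, 24, 51), 1)
    pr <- nn_distance_profile(random_permutation_pair(n))
    i <- sample(2:(n - 2), 1)
    h <- pr$d[sample(n, 1), seq_len(i - 1)]
    ct <- conditional_table(n, i, h)
    expect_equal(sum(ct$p), 1, tolerance = 1e-10)
    expect_identical(ct$d[1], utils::tail(h, 1)) # distances cannot decrease
    expect_gte(min(ct$p), 0)
  }
})

test_that("results are identical with the cache disabled", {
  nn_cache_clear()
  ct_cached <- conditional_table(30, 5, c(1, 2, 2, 2))
  tab_cached <- marginal_table(30)
  withr::with_options(list(nnindep.cache = FALSE), {
    nn_cache_clear()
    expect_equal(conditional_table(30, 5, c(1, 2, 2, 2)), ct_cached)
    expect_equal(marginal_table(30), tab_cached)
  })
})

test_that("entropy and the entropy-guided depth behave as documented", {
  expect_equal(entropy(c(0, 1, 0)), 0)
  expect_equal(entropy(rep(1 / 7, 7)), log(7))
  expect_error(entropy(c(-0.1, 1.1)), "negative")
  H <- apply(marginal_table(320), 1, entropy)
  i_star <- default_i_max(320)
  expect_gte(i_star, 1)
  expect_lte(i_star, 319)
  expect_lt(i_star, 300) # well below n - 1: tail entropies rise
  # nonincreasing from the entropy peak up to the returned depth
  pk <- which.max(H)
  expect_true(all(diff(H[pk:i_star]) <= 1e-9))
  # and the tail is non-monotone: entropies rise again beyond the minimum
  expect_gt(max(H[i_star:319]) , H[i_star] + 1e-9)
})

test_that("log-space counting stays finite up to n = 2000", {
  tab <- marginal_table(2000)
  expect_true(all(is.finite(tab)))
  expect_equal(rowSums(tab), rep(1, 1999), tolerance = 1e-8,
               ignore_attr = TRUE)
  d_star <- which.max(tab[99, ]) # modal D_99 distance
  ct <- conditional_table(2000, 100,
                          c(d_star - 2, d_star - 1, d_star, d_star))
  expect_equal(sum(ct$p), 1, tolerance = 1e-10)
})

test_that("Monte-Carlo frequencies are reproducible and match the exact marginals", {
  f1 <- monte_carlo_frequency(20, 3, reps = 1000, seed = 9)
  f2 <- monte_carlo_frequency(20, 3, reps = 1000, seed = 9)
  expect_identical(f1, f2)
  expect_equal(sum(f1), 1)
  f <- monte_carlo_frequency(20, 3, reps = 20000, seed = 1)
  p <- marginal_table(20)[3, ]
  se <- sqrt(p * (1 - p) / 20000)
  big <- p * 20000 >= 5 # cells where the binomial-normal approximation holds
  expect_true(all(abs(f[big] - p[big]) <= 4 * se[big]))
  expect_error(brute_force_distribution(10), "enumerate")
})
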