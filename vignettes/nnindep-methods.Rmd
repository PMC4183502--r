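---
title: "Exact nearest-neighbour distance distributions on the rank torus and the tests built on them"
author: "nnindep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact nearest-neighbour distance distributions on the rank torus and the tests built on them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnindep)
```

## The model

Given `n` paired observations `(x_k, y_k)`, replace each coordinate by its
rank.  Ties are broken uniformly at random (seeded): the exact
distributions below require genuine permutations, and deterministic
mid-ranks would put two points on one grid line.  The rank-transformed
sample is a pair of permutations of `{0, ..., n-1}`: `n` points on an
`n x n` grid with exactly one point on every horizontal and every vertical
line.  Under the null hypothesis of independence both permutations are
uniform, so all `(n-1)!` configurations relative to any reference point
are equally likely.

We endow the grid with the *torus Chebyshev metric*: the distance between
points is the larger of the two per-axis wraparound distances
`delta(u, v) = min(|u - v|, n - |u - v|)`.  The torus makes the metric
translation invariant, so one exact distribution applies to every sample
point; the price is a bias relative to plane geometry for points near the
boundary of real (non-periodic) data, which shrinks for close neighbours.
For a reference point, let `D_1 <= D_2 <= ... <= D_{n-1}` denote the
sorted distances to the other points; distances live in
`1..floor(n/2)`.

## Exact distributions by counting admissible configurations

Fix the reference at the origin.  The other `n - 1` points form a
uniformly random bijection between the remaining columns and rows.  A
coordinate `u` has axis distance `delta(u) in 1..floor(n/2)`; for
`d < n/2` exactly two columns (and two rows) lie at axis distance `d`,
while for even `n` the antipodal shell `d = n/2` has a single column and
row.  A point is at distance exactly `d` when the larger of its two axis
distances is `d`, which requires one of its grid lines to lie on the
distance-`d` *border region*.  Since at most two columns and two rows sit
on that border, **at most four points can be at any exact distance** — the
combinatorial fact that shapes everything downstream (at most two on the
degenerate antipodal border of an even torus, where the border collapses
to one horizontal plus one vertical line; the implementation branches on
parity and the enumeration oracle arbitrates).

Counting proceeds shell by shell.  After all shells up to `d` are
populated, an equal number `F` of columns and rows within distance `d`
remain open, and each must eventually pair with a line from a farther
shell.  Placing `e` border points splits them into corners (new column and
new row), column-edge points (new column, open interior row) and row-edge
points (open interior column, new row); summing the split yields the
closed-form border count `region_r_combinations()`.  Points beyond the
last constrained shell pair the open lines injectively with outer lines
and biject the remainder, a falling-factorial product.  The product of
shell factors gives the number of configurations realizing a prescribed
distance prefix (`count_admissible()`), hence

* the joint law `prob_joint()` = count / `(n-1)!`,
* the exact CDF `prob_survival()` and marginals `marginal_table()`
  (two independent routes that must agree),
* conditional laws `conditional_table()`.

All products of factorials are evaluated through `lgamma` in log space;
the counting stays finite and normalized at least up to `n = 2000`
(tested).  Everything is validated against `brute_force_distribution()`,
which enumerates all `(n-1)!` configurations exactly for `n <= 9`, and
against Monte-Carlo frequencies (`monte_carlo_frequency()`) for larger
`n`.

**Markov structure.**  A border holds at most four points, so the trailing
run of equal values in the distance history can never exceed four.  The
conditional law of the next distance depends on the history only through
the last value, its trailing run length, and the neighbour index — which
the last four history entries always determine.  The distance sequence is
therefore a Markov chain of order 4; the package conditions on the last
`min(4, i - 1)` distances and keeps the full-history ratio-of-joints route
(`prob_conditional()`) as a cross-check.  Conditional tables are cached by
`(n, i, last value, run length)`; caching is transparent and can be
disabled with `options(nnindep.cache = FALSE)`.

**How deep to look: `default_i_max()`.**  The marginal entropies `H(D_i)`
rise marginally from `i = 1` to an early peak, then decrease steadily as
the distributions narrow, and finally fluctuate upwards close to
`i = n - 1` where the maximal-distance bound constrains the sequence.
The default depth is the first local entropy minimum scanning from the
peak onward (absolute tolerance 1e-9 against floating-point wiggle):
9, 25, 63 and 247 for `n` = 20, 50, 100 and 320.  Indices beyond it carry
almost no information; the value is a default, not a cap — every test
accepts an `i_max` override.

## The two tests

**Chi-squared distributional test.**  For each neighbour index `i`, the
observed distances `d_i(z_k)` across the sample are compared with the
mixture obtained by drawing a point uniformly and then drawing `D_i` from
its exact conditional law given that point's observed previous (last-4)
distances: `pbar(d) = (1/n) sum_k P(D_i = d | history_k)`.  Pearson's
statistic `T_i = sum_d (n f(d) - n pbar(d))^2 / (n pbar(d))` is referred
to a chi-squared law with `m - 1` degrees of freedom (`m` = support size
of `pbar`); by construction every observed distance has positive `pbar`,
so the statistic never divides by zero.  The per-index p-values are
combined over the whole neighbour sequence by a Fisher-type sum on the
log scale, `S = sum_i(-log pval_i)`, computed with
`pchisq(log.p = TRUE)` so that strong signals do not underflow into
ties; using every depth simultaneously — rather than a single fixed
neighbour index or only the most extreme component — is the point of the
construction.  The chi-squared reference treats the `n`
observations as independent draws, which they are not: points share
pairwise distances and obey the one-point-per-line constraints.  In exact
simulation the effect is conservative (null p-values stochastically larger
than uniform, mean around 0.8), which is why rejection decisions use
empirical calibration rather than the nominal reference.

**Extreme-path location test.**  Weakly dependent samples rarely shift the
bulk of the neighbour-distance distribution; the signal concentrates in a
few points with extreme paths.  For every point and index the test
computes the exact two-sided p-value of the observed distance under the
*marginal* law of `D_i` — `q = min(1, 2 min(P(D_i <= d), P(D_i >= d)))`,
both tails including the observed atom, so `q in (0, 1]` despite
discreteness — takes the minimum over points per index, and sums the
per-index evidence: `E = sum_i(-log min_k q[k, i])`.  Conditioning these
p-values on each point's own
history was considered and rejected: a strongly dependent sample (e.g. a
perfect diagonal) is locally unsurprising at every step of its own path,
and such a variant demonstrably loses the diagonal entirely, while the
location comparison against the marginal law detects it at many null
standard deviations.

**Calibration.**  Both aggregates are monotone transforms of a minimum
p-value over dependent components, so their null laws are not standard;
`calibrate_null()` draws `B` random permutation pairs, sets the cutoff at
the `ceiling((1 - alpha) * B)`-th order statistic and reports empirical
p-values `(r + 1)/(B + 1)` (never zero).  This neutralizes the choice of
aggregate and the conservativeness of the nominal chi-squared reference.
`test_independence()` wires the whole pipeline together and records every
seed.  Both statistics depend on the data only through the ranks, so they
are invariant under strictly increasing transformations of either
variable.

## The benchmark framework

Dependencies are calibrated to a common mutual-information (MI) scale so
that power curves of different shapes are comparable.  All MI values are
in nats.

* **Functional kinds**: `x ~ U(0,1)`, `y = f(x) + N(0, sigma^2)` with `f`
  linear, centred quadratic `4(x - 1/2)^2`, centred cubic
  `128(x-1/3)^3 - 48(x-1/3)^2 - 12(x-1/3)`, sine of period 0.5
  (`sin(4 pi x)`), fourth root, and the half-step `1(x > 1/2)`; these
  constants are frozen in `R/benchmark.R`.  The circle draws a uniform
  angle on the radius-1 circle and adds isotropic Gaussian noise to both
  coordinates (`y` is not a function of `x`, so noise on one coordinate
  alone would be arbitrary).  `independent` is pure product noise for
  null rows.
* **MI by grid discretization** (`grid_density()`,
  `mutual_information_grid()`): piecewise-constant density on an `m x m`
  grid, `m = 300` by default — uniform mass per `x`-column (midpoint
  rule), exact Gaussian CDF differences across `y`-cells, range extended
  8 standard deviations, cells renormalized (the truncated tails carry
  ~1e-15).  A convergence check (`m` 200 vs 400 within 2%) guards the
  resolution choice.  `calibrate_sigma()` bisects on `sigma` (MI is
  monotone decreasing in noise), default tolerance 0.005 nats.
* **Patchwork copulas** (`patchwork_build()`): a `g x g` grid (default
  `g = 4`) of rectangles with uneven breakpoints chosen as the cumulative
  row/column sums of a nonnegative weight matrix, which makes both
  marginals exactly uniform and gives the closed form
  `MI = sum p_ij log(p_ij / (a_i b_j))`.  `patchwork_search()` draws
  normalized `runif^concentration` weight proposals until the closed-form
  MI is within tolerance of the target (cap 1e5 proposals, failure reports
  the best MI found; the bound `log g` is attained only by
  permutation-support weights).  For the two-route MI check the grid
  density of a patchwork is built on the product refinement of the
  copula's own breakpoints, where discretized and closed-form MI coincide
  exactly; a regular grid that ignores the breakpoints could not meet a
  1e-6 tolerance.
* **Geometry**: `project_to_torus()` tags unit-square samples for toroidal
  nearest-neighbour profiles.  The package's tests operate on the torus
  always — that is where their exact null laws hold.  Wrapped external
  measures receive untransformed coordinates; adapting them to the torus
  is out of scope and a known limitation.
* **Power protocol** (`estimate_power()`): a reference ensemble of
  independent uniform samples fixes the `(1 - alpha)` empirical cutoff;
  power is the fraction of test-ensemble statistics above it.  Reference
  and test ensembles use disjoint recorded seed streams.  `roc_points()`
  sweeps the pooled statistics into an ROC staircase.  External measures
  (distance correlation, Hoeffding's D, MIC) are wrapped behind
  `evaluate_method()` and require their optional packages; a missing
  backend is an explicit error, never a silent fallback, and their
  internals are deliberately not reimplemented here.  A Kraskov-type MI
  estimator can be plugged in via `options$estimator`.

## Problem sizes, numerical choices, degenerate inputs

* Exactness is asserted against full enumeration for `n = 3..7`
  (every admissible prefix, tolerance 1e-12) and the order-4 Markov
  property against enumeration at `n = 8`; Monte-Carlo agreement uses
  1e5 configurations at `n = 20` and `50` (4 binomial standard errors per
  adequately filled cell, total variation under 0.005).
* Calibration checks run at reduced but honest sizes: 200 reference + 200
  fresh null samples at `n = 100` for the 99% binomial band around the 5%
  level, and 100 test + 100 reference samples of `n = 320` per MI target
  for the circle power curve over MI {0.01, 0.02, 0.03, 0.05}.  "Reaches
  its maximum power" is judged within Monte-Carlo resolution: powers
  within two binomial standard errors of the maximum (floored at one
  rejection) count as on the plateau.  Full 500 + 500 ensembles over the
  complete kind-by-MI grid are supported by `cmd_benchmark()` (resumable
  TSV output) but are long runs by design.
* Degenerate cases: a single-distance chi-squared support gives
  `T = 0, df = 0, p = 1` and is flagged; conditioning on a
  zero-probability history is an error (caller misuse), not probability
  zero; inadmissible distance prefixes (decreasing, runs longer than the
  border holds) count zero configurations.
* Entropy is reported in nats (natural log) everywhere, matching the MI
  scale.

## What the generators do and do not emulate

The synthetic benchmark draws exchangeable i.i.d. samples with exactly
known dependence strength, clean uniform margins and seeded
reproducibility.  Real data differ in ways the benchmark does not model:
heavy ties (rank tie-breaking injects randomness), missingness (handled by
pairwise-complete filters in `cmd_screen()`, not modelled), plane rather
than torus geometry (boundary bias for far neighbours; the entropy-guided
depth keeps the statistic concentrated on close neighbours where the bias
is small), and serial or cluster dependence between observations, which
none of the exact laws cover.  Passing the package's tests therefore
demonstrates correctness of the mathematics and calibration under the
stated model, not robustness to violations of exchangeability.

## Known limitations

* The exact laws are intrinsically toroidal; no Euclidean-plane boundary
  correction is attempted.
* Runtime of the exact machinery grows with `n` (the per-`n` tables are
  cached); samples beyond a few thousand points are outside the intended
  regime.
* The benchmark's external competitors are only available when their
  packages are installed; the bundled comparisons otherwise cover
  Pearson's correlation and the two nearest-neighbour tests.
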