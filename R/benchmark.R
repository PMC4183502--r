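# Benchmark framework: mutual-information-calibrated functional
# dependencies, patchwork copulas, toroidal projection, and the
# empirical-cutoff power / ROC harness over pluggable dependence measures.

.functional_kinds <- c("linear", "quadratic", "cubic", "sine_p05", "circle",
                       "fourth_root", "step", "independent")
.dependence_kinds <- c(.functional_kinds, "patchwork")

# Frozen functional forms.  These follow the classic benchmark family of
# curves on the unit interval (linear, centred quadratic/cubic, sine of
# period 0.5, fourth root, half-step); the circle is handled separately
# (uniform angle on the unit circle, isotropic noise on both coordinates).
.dep_fun <- function(kind) {
  switch(kind,
    linear = function(x) x,
    quadratic = function(x) 4 * (x - 0.5)^2,
    cubic = function(x) 128 * (x - 1 / 3)^3 - 48 * (x - 1 / 3)^2 -
      12 * (x - 1 / 3),
    sine_p05 = function(x) sin(4 * pi * x),
    fourth_root = function(x) x^0.25,
    step = function(x) as.numeric(x > 0.5),
    independent = function(x) rep(0, length(x)),
    .stopf("'%s' has no functional form", kind))
}

#' Specify a benchmark dependence
#'
#' A dependence between paired variables, either functional
#' (`y = f(x) + noise` with `x` uniform; the circle uses a uniform angle
#' with isotropic noise on both coordinates) or a [patchwork_build()]
#' copula.  Exactly one of `sigma` (functional kinds) or `copula`
#' (patchwork kind) must be populated.
#'
#' @param kind one of `"linear"`, `"quadratic"`, `"cubic"`, `"sine_p05"`
#'   (sine with period 0.5), `"circle"`, `"fourth_root"`, `"step"`,
#'   `"independent"` (pure noise), `"patchwork"`.
#' @param sigma Gaussian noise standard deviation, `>= 0` (functional
#'   kinds).
#' @param copula a `"patchwork_copula"` (patchwork kind).
#' @param target_mi optional mutual-information target this spec was
#'   calibrated to (bookkeeping).
#' @param geometry `"euclidean"` or `"torus"`; see [project_to_torus()].
#' @return an object of class `"dependence_spec"`.
#' @export
dependence_spec <- function(kind, sigma = NULL, copula = NULL,
                            target_mi = NULL,
                            geometry = c("euclidean", "torus")) {
  kind <- match.arg(kind, .dependence_kinds)
  geometry <- match.arg(geometry)
  if (kind == "patchwork") {
    if (!inherits(copula, "patchwork_copula"))
      .stopf("patchwork kind requires a patchwork_copula")
    if (!is.null(sigma)) .stopf("sigma does not apply to the patchwork kind")
  } else {
    if (!is.null(copula)) .stopf("copula applies to the patchwork kind only")
    if (is.null(sigma) || !is.numeric(sigma) || sigma < 0)
      .stopf("functional kinds require sigma >= 0")
  }
  structure(list(kind = kind, sigma = sigma, copula = copula,
                 target_mi = target_mi, geometry = geometry),
            class = "dependence_spec")
}

#' @export
print.dependence_spec <- function(x, ...) {
  par <- if (x$kind == "patchwork")
    sprintf("g = %d, closed-form MI = %.4f", x$copula$g, x$copula$mi)
  else sprintf("sigma = %.4g", x$sigma)
  cat(sprintf("dependence spec: %s (%s), %s geometry%s\n", x$kind, par,
              x$geometry,
              if (!is.null(x$target_mi))
                sprintf(", MI target %.3g", x$target_mi) else ""))
  invisible(x)
}

#' Sample from a functional dependence
#'
#' Draws `x ~ U(0, 1)` i.i.d. and `y = f(x) + eps`, `eps ~ N(0, sigma^2)`.
#' The circle kind instead draws a uniform angle `theta` on the radius-1
#' circle and adds isotropic Gaussian noise to both coordinates
#' (`y` is not a function of `x` there).
#'
#' @param spec a functional [dependence_spec()].
#' @param n_points number of points.
#' @param seed integer seed (deterministic given the seed).
#' @return list with numeric `x`, `y` and the spec's `geometry`.
#' @export
sample_functional <- function(spec, n_points, seed = 1L) {
  stopifnot(inherits(spec, "dependence_spec"))
  if (!spec$kind %in% .functional_kinds)
    .stopf("sample_functional() handles functional kinds, not '%s'", spec$kind)
  if (!.is_count(n_points, 2L)) .stopf("n_points must be an integer >= 2")
  .with_seed(seed, {
    if (spec$kind == "circle") {
      theta <- stats::runif(n_points, 0, 2 * pi)
      x <- cos(theta) + stats::rnorm(n_points, sd = spec$sigma)
      y <- sin(theta) + stats::rnorm(n_points, sd = spec$sigma)
    } else {
      x <- stats::runif(n_points)
      y <- .dep_fun(spec$kind)(x) + stats::rnorm(n_points, sd = spec$sigma)
    }
    list(x = x, y = y, geometry = spec$geometry)
  })
}

#' Sample from any benchmark dependence
#'
#' Dispatches to [sample_functional()] or [patchwork_sample()].
#'
#' @inheritParams sample_functional
#' @export
sample_dependence <- function(spec, n_points, seed = 1L) {
  stopifnot(inherits(spec, "dependence_spec"))
  if (spec$kind == "patchwork") {
    s <- patchwork_sample(spec$copula, n_points, seed)
    s$geometry <- spec$geometry
    s
  } else sample_functional(spec, n_points, seed)
}

# ---- grid densities and mutual information ---------------------------------

#' Piecewise-constant grid approximation of a dependence density
#'
#' Discretizes the model density of a benchmark dependence on a product
#' grid so that its mutual information can be computed in closed form.
#' Functional kinds use a regular `m x m` grid: the `x`-marginal is uniform
#' (midpoint rule per column), and the Gaussian noise mass is integrated
#' exactly across `y`-cells from normal CDF differences, with the `y`-range
#' extended 8 standard deviations beyond the range of `f`.  The circle kind
#' integrates over a fine uniform grid of angles (2048 midpoints).  The
#' patchwork kind returns the product refinement of the copula's own
#' breakpoints (about `m` cells per axis), on which the discretized mutual
#' information equals the copula's closed form exactly.  Cell masses are
#' renormalized to sum to one (the truncated Gaussian tails carry ~1e-15).
#'
#' @param spec a [dependence_spec()]; functional kinds need `sigma > 0`.
#' @param m grid resolution per axis (default 300).
#' @return an object of class `"grid_density"` with `x_breaks`, `y_breaks`
#'   and the cell-probability matrix `q` (rows index `x`-cells).
#' @export
grid_density <- function(spec, m = 300L) {
  stopifnot(inherits(spec, "dependence_spec"))
  if (!.is_count(m, 2L)) .stopf("m must be an integer >= 2")
  if (spec$kind == "patchwork") {
    cop <- spec$copula
    s <- max(1L, ceiling(m / cop$g))
    q <- kronecker(cop$p, matrix(1 / s^2, s, s))
    refine <- function(br) {
      out <- unlist(lapply(seq_len(length(br) - 1L), function(i)
        br[i] + (br[i + 1L] - br[i]) * seq_len(s) / s))
      c(br[1L], out)
    }
    gd <- list(kind = spec$kind, m = nrow(q), x_breaks = refine(cop$x_breaks),
               y_breaks = refine(cop$y_breaks), q = q)
    return(structure(gd, class = "grid_density"))
  }
  sigma <- spec$sigma
  if (sigma <= 0)
    .stopf("grid_density() needs sigma > 0 (the noiseless density is singular)")
  if (spec$kind == "circle") {
    lim <- 1 + 8 * sigma
    xb <- seq(-lim, lim, length.out = m + 1L)
    theta <- (seq_len(2048L) - 0.5) / 2048L * 2 * pi
    Px <- vapply(seq_len(m), function(a) {
      stats::pnorm(xb[a + 1L], cos(theta), sigma) -
        stats::pnorm(xb[a], cos(theta), sigma)
    }, numeric(length(theta)))
    Py <- vapply(seq_len(m), function(b) {
      stats::pnorm(xb[b + 1L], sin(theta), sigma) -
        stats::pnorm(xb[b], sin(theta), sigma)
    }, numeric(length(theta)))
    q <- crossprod(Px, Py) / length(theta)
    yb <- xb
  } else {
    xb <- seq(0, 1, length.out = m + 1L)
    fx <- .dep_fun(spec$kind)((xb[-1L] + xb[-(m + 1L)]) / 2)
    yb <- seq(min(fx) - 8 * sigma, max(fx) + 8 * sigma, length.out = m + 1L)
    q <- t(vapply(fx, function(f) {
      diff(stats::pnorm(yb, mean = f, sd = sigma)) / m
    }, numeric(m)))
  }
  q <- q / sum(q)
  structure(list(kind = spec$kind, m = m, x_breaks = xb, y_breaks = yb, q = q),
            class = "grid_density")
}

#' Mutual information of a grid density
#'
#' `MI = sum_cells q * log(q / (q_x * q_y))` in nats, with `q_x`, `q_y` the
#' row and column marginals; zero-mass cells contribute nothing.
#'
#' @param density a [grid_density()].
#' @return mutual information in nats, `>= 0`.
#' @export
mutual_information_grid <- function(density) {
  stopifnot(inherits(density, "grid_density"))
  q <- density$q
  prod_marg <- outer(rowSums(q), colSums(q))
  pos <- q > 0
  sum(q[pos] * log(q[pos] / prod_marg[pos]))
}

#' Calibrate the noise level to a mutual-information target
#'
#' Finds `sigma` with `|MI(sigma) - target_mi| <= tol` for a functional
#' dependence kind by bisection, exploiting that the grid mutual
#' information decreases monotonically in the noise level.  The upper
#' bracket is doubled from 0.25 until the MI falls below the target (cap
#' 2^12); the lower bracket is halved from 1e-3 until the MI exceeds it.
#'
#' @param kind a functional dependence kind (not `"independent"`).
#' @param target_mi desired mutual information in nats, `> 0`.
#' @param tol absolute MI tolerance (default 0.005).
#' @param m grid resolution passed to [grid_density()].
#' @return the calibrated `sigma`, with attributes `mi` (achieved value)
#'   and `iterations`.
#' @export
calibrate_sigma <- function(kind, target_mi, tol = 0.005, m = 300L) {
  kind <- match.arg(kind, setdiff(.functional_kinds, "independent"))
  if (!is.numeric(target_mi) || target_mi <= 0) .stopf("target_mi must be > 0")
  mi_at <- function(sigma)
    mutual_information_grid(grid_density(dependence_spec(kind, sigma), m))
  lo <- 1e-3
  while (mi_at(lo) <= target_mi) {
    lo <- lo / 2
    if (lo < 1e-8)
      .stopf("target MI %.4g unattainable for kind '%s' (above the noiseless bound)",
             target_mi, kind)
  }
  hi <- 0.25
  while (mi_at(hi) >= target_mi) {
    hi <- hi * 2
    if (hi > 4096) .stopf("no noise level this large reaches MI %.4g", target_mi)
  }
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    mi <- mi_at(mid)
    if (abs(mi - target_mi) <= tol || it >= 80L) break
    if (mi > target_mi) lo <- mid else hi <- mid
  }
  if (abs(mi - target_mi) > tol)
    .stopf("bisection did not reach MI %.4g within tol %.4g", target_mi, tol)
  structure(mid, mi = mi, iterations = it)
}

# ---- patchwork copulas -----------------------------------------------------

#' Build a patchwork copula
#'
#' A piecewise-constant bivariate density on a `g x g` grid with uneven
#' cell spacing chosen so that both marginals are uniform: cell `(i, j)`
#' carries probability `p[i, j]` on a rectangle of width `a[i] = sum_j
#' p[i, j]` and height `b[j] = sum_i p[i, j]` (breakpoints are the
#' cumulative row/column sums).  Its mutual information has the closed
#' form `MI = sum p[i, j] * log(p[i, j] / (a[i] * b[j]))`.
#'
#' @param g grid size, `>= 1`.
#' @param weights nonnegative `g x g` matrix (or length-`g^2` vector), not
#'   all zero.
#' @param normalize divide the weights by their sum (default TRUE; if
#'   FALSE they must already sum to 1).
#' @return an object of class `"patchwork_copula"` with fields `g`, `p`,
#'   `a`, `b`, `x_breaks`, `y_breaks`, `mi`.
#' @export
patchwork_build <- function(g, weights, normalize = TRUE) {
  if (!.is_count(g, 1L)) .stopf("g must be a positive integer")
  p <- matrix(as.numeric(weights), g, g)
  if (any(!is.finite(p)) || any(p < 0)) .stopf("weights must be nonnegative")
  tot <- sum(p)
  if (tot <= 0) .stopf("weights must not be all zero")
  if (normalize) p <- p / tot
  else if (abs(tot - 1) > 1e-8) .stopf("weights must sum to 1 when normalize = FALSE")
  a <- rowSums(p)
  b <- colSums(p)
  pos <- p > 0
  mi <- sum(p[pos] * log(p[pos] / outer(a, b)[pos]))
  structure(list(g = g, p = p, a = a, b = b,
                 x_breaks = c(0, cumsum(a)), y_breaks = c(0, cumsum(b)),
                 mi = mi),
            class = "patchwork_copula")
}

#' @export
print.patchwork_copula <- function(x, ...) {
  cat(sprintf("patchwork copula on a %d x %d grid, MI = %.4f nats\n",
              x$g, x$g, x$mi))
  invisible(x)
}

#' Search for a patchwork copula with a given mutual information
#'
#' Repeatedly draws i.i.d. weight proposals, normalizes them, evaluates the
#' closed-form mutual information, and returns the first copula within
#' `tol` of the target.  Proposals are `runif(g^2)^concentration`: larger
#' `concentration` skews the weights and reaches higher MI targets (the
#' attainable maximum is `log(g)`, reached only by permutation-support
#' weights).
#'
#' @param g grid size.
#' @param target_mi desired mutual information, `0 <= target_mi < log(g)`
#'   attainable.
#' @param tol absolute MI tolerance (default 0.005).
#' @param seed integer seed (deterministic given the seed).
#' @param concentration proposal skew exponent (default 1).
#' @param max_proposals iteration cap (default 1e5).
#' @return a `"patchwork_copula"` within `tol`, with attribute
#'   `n_proposals`.  If the cap is exceeded an error reports the best MI
#'   found.
#' @export
patchwork_search <- function(g = 4L, target_mi, tol = 0.005, seed = 1L,
                             concentration = 1, max_proposals = 1e5L) {
  if (!is.numeric(target_mi) || target_mi < 0) .stopf("target_mi must be >= 0")
  if (g > 1L && target_mi >= log(g))
    .stopf("target MI %.4g is not attainable on a %d x %d grid (bound log(g) = %.4g)",
           target_mi, g, g, log(g))
  .with_seed(seed, {
    best <- NULL
    best_gap <- Inf
    for (it in seq_len(max_proposals)) {
      cop <- patchwork_build(g, stats::runif(g * g)^concentration)
      gap <- abs(cop$mi - target_mi)
      if (gap < best_gap) { best <- cop; best_gap <- gap }
      if (gap <= tol) {
        attr(cop, "n_proposals") <- it
        return(cop)
      }
    }
    .stopf("no copula within tol %.4g of MI %.4g in %d proposals (best: MI %.4g)",
           tol, target_mi, max_proposals, best$mi)
  })
}

#' Sample from a patchwork copula
#'
#' Selects a grid rectangle with its copula probability, then draws a
#' uniform point inside it.  Both marginals are uniform on `[0, 1]`.
#'
#' @param copula a [patchwork_build()] result.
#' @param n_points number of points.
#' @param seed integer seed.
#' @return list with numeric `x`, `y` in `[0, 1]`.
#' @export
patchwork_sample <- function(copula, n_points, seed = 1L) {
  stopifnot(inherits(copula, "patchwork_copula"))
  if (!.is_count(n_points, 1L)) .stopf("n_points must be a positive integer")
  g <- copula$g
  .with_seed(seed, {
    cell <- sample.int(g * g, n_points, replace = TRUE, prob = as.vector(copula$p))
    i <- (cell - 1L) %% g + 1L
    j <- (cell - 1L) %/% g + 1L
    list(x = copula$x_breaks[i] + stats::runif(n_points) * copula$a[i],
         y = copula$y_breaks[j] + stats::runif(n_points) * copula$b[j])
  })
}

#' Mark a unit-square sample as toroidal
#'
#' Tags a sample so that downstream nearest-neighbour profiles use the
#' toroidal metric (wraparound on both axes).  The nearest-neighbour tests
#' of this package always operate on the torus after rank transformation --
#' that is the geometry under which their exact null distributions hold --
#' so the tag matters when comparing plane- versus torus-geometry profiles.
#' Wrapped external measures (correlation, distance correlation, ...)
#' always receive the untransformed coordinates: adapting them to the
#' torus is out of scope, a documented limitation.
#'
#' @param x,y numeric vectors in `[0, 1]`.
#' @return list with `x`, `y`, `geometry = "torus"`.
#' @export
project_to_torus <- function(x, y) {
  if (any(x < 0 | x > 1, na.rm = TRUE) || any(y < 0 | y > 1, na.rm = TRUE))
    .stopf("project_to_torus() expects unit-square data")
  list(x = x, y = y, geometry = "torus")
}

# ---- method wrappers and the power harness ---------------------------------

.benchmark_methods <- c("pearson", "dcor", "hoeffd", "kraskov_mi", "mic",
                        "novel_chisq", "novel_ext")

.require_backend <- function(method, pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    .stopf("method '%s' unavailable: it requires the optional package '%s'",
           method, pkg)
}

#' Evaluate a dependence measure on paired data
#'
#' One interface over the benchmarked measures; every method returns a
#' scalar in which larger means more dependence.  `pearson` is the squared
#' product-moment correlation; `dcor`, `hoeffd` and `mic` wrap the
#' optional packages \pkg{energy}, \pkg{Hmisc} and \pkg{minerva} and fail
#' with an explicit message when the backend is not installed (their
#' internals are deliberately not reimplemented here); `kraskov_mi`
#' requires a user-supplied estimator via `options$estimator` for the same
#' reason.  `novel_chisq` and `novel_ext` are this package's tests
#' (statistic only; calibrate cutoffs with [calibrate_null()] or
#' [estimate_power()]).
#'
#' @param name method name, one of `pearson`, `dcor`, `hoeffd`,
#'   `kraskov_mi`, `mic`, `novel_chisq`, `novel_ext`.
#' @param x,y complete paired numeric vectors.
#' @param options list of method options: `i_max`, `tie_seed` (novel
#'   methods), `estimator` (a `function(x, y)`, for `kraskov_mi`).
#' @return a finite scalar statistic.
#' @export
evaluate_method <- function(name, x, y, options = list()) {
  name <- match.arg(name, .benchmark_methods)
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) .stopf("complete paired data required")
  novel <- function(method) {
    i_max <- options$i_max
    if (is.null(i_max)) i_max <- default_i_max(length(x))
    tie_seed <- if (is.null(options$tie_seed)) 1L else options$tie_seed
    .nn_statistic(method, i_max)(as_permutation_pair(x, y, tie_seed))
  }
  switch(name,
    pearson = stats::cor(x, y)^2,
    dcor = {
      .require_backend("dcor", "energy")
      energy::dcor(x, y)
    },
    hoeffd = {
      .require_backend("hoeffd", "Hmisc")
      Hmisc::hoeffd(x, y)$D[1L, 2L]
    },
    mic = {
      .require_backend("mic", "minerva")
      minerva::mine_stat(x, y, measure = "mic")
    },
    kraskov_mi = {
      if (!is.function(options$estimator))
        .stopf("method 'kraskov_mi' unavailable: supply options$estimator (no estimator is bundled)")
      options$estimator(x, y)
    },
    novel_chisq = novel("chisq"),
    novel_ext = novel("extreme"))
}

#' Estimate the power of a method against a dependence
#'
#' Implements the empirical-cutoff protocol: a reference ensemble of
#' `n_ref` independent samples (both coordinates i.i.d. uniform) yields the
#' `(1 - alpha)` cutoff of the method's statistic; the power is the
#' fraction of `n_test` samples from `spec` whose statistic exceeds that
#' cutoff.  Reference and test ensembles use disjoint seed streams derived
#' from `seed` and recorded in the result.
#'
#' @param method a method name for [evaluate_method()].
#' @param spec a [dependence_spec()].
#' @param n_points points per sample.
#' @param n_test,n_ref ensemble sizes, each `>= 20`.
#' @param alpha significance level.
#' @param seed integer master seed.
#' @param options method options for [evaluate_method()].
#' @return an object of class `"power_result"`: `method`, `kind`, `mi`,
#'   `power`, `cutoff`, the ensemble sizes, `alpha` and `seeds`.
#' @export
estimate_power <- function(method, spec, n_points = 320L, n_test = 100L,
                           n_ref = 100L, alpha = 0.05, seed = 1L,
                           options = list()) {
  stopifnot(inherits(spec, "dependence_spec"))
  if (!.is_count(n_test, 20L) || !.is_count(n_ref, 20L))
    .stopf("n_test and n_ref must be integers >= 20")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    .stopf("alpha must lie strictly between 0 and 1")
  ref_seed <- seed
  test_seed <- seed + 500000L
  ref <- vapply(seq_len(n_ref), function(b) {
    s <- .with_seed(ref_seed + b, list(x = stats::runif(n_points),
                                       y = stats::runif(n_points)))
    evaluate_method(method, s$x, s$y, options)
  }, numeric(1L))
  test <- vapply(seq_len(n_test), function(b) {
    s <- sample_dependence(spec, n_points, seed = test_seed + b)
    evaluate_method(method, s$x, s$y, options)
  }, numeric(1L))
  cutoff <- sort(ref)[ceiling((1 - alpha) * n_ref)]
  mi <- if (spec$kind == "patchwork") spec$copula$mi else spec$target_mi
  structure(list(method = method, kind = spec$kind, mi = mi,
                 sigma = spec$sigma, n_points = n_points, n_test = n_test,
                 n_ref = n_ref, alpha = alpha, cutoff = cutoff,
                 power = mean(test > cutoff),
                 seeds = c(master = seed, reference = ref_seed,
                           test = test_seed)),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("power of %s on %s (MI %s): %.3f (n = %d, %d test / %d reference, alpha = %.2g)\n",
              x$method, x$kind,
              if (is.null(x$mi)) "?" else format(x$mi, digits = 3),
              x$power, x$n_points, x$n_test, x$n_ref, x$alpha))
  invisible(x)
}

#' Receiver operating curve of a method against a dependence
#'
#' Sweeps a rejection threshold over the pooled reference and test
#' statistics and reports the false/true positive rates, a monotone
#' staircase from (0, 0) to (1, 1).
#'
#' @inheritParams estimate_power
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(method, spec, n_points = 320L, n_test = 100L,
                       n_ref = 100L, seed = 1L, options = list()) {
  stopifnot(inherits(spec, "dependence_spec"))
  ref <- vapply(seq_len(n_ref), function(b) {
    s <- .with_seed(seed + b, list(x = stats::runif(n_points),
                                   y = stats::runif(n_points)))
    evaluate_method(method, s$x, s$y, options)
  }, numeric(1L))
  test <- vapply(seq_len(n_test), function(b) {
    s <- sample_dependence(spec, n_points, seed = seed + 500000L + b)
    evaluate_method(method, s$x, s$y, options)
  }, numeric(1L))
  th <- sort(unique(c(ref, test)))
  out <- data.frame(threshold = c(Inf, rev(th)),
                    fpr = c(0, vapply(rev(th), function(t) mean(ref >= t),
                                      numeric(1L))),
                    tpr = c(0, vapply(rev(th), function(t) mean(test >= t),
                                      numeric(1L))))
  out
}
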