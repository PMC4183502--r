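# MI-calibrated dependence generators, patchwork copulas, and the power
# harness.

test_that("functional samples follow their noiseless curves and uniform base", {
  s <- sample_functional(dependence_spec("linear", sigma = 0), 200, seed = 1)
  expect_equal(s$y, s$x)
  s <- sample_functional(dependence_spec("circle", sigma = 0), 200, seed = 2)
  expect_equal(sqrt(s$x^2 + s$y^2), rep(1, 200), tolerance = 1e-12)
  s <- sample_functional(dependence_spec("step", sigma = 0), 50, seed = 3)
  expect_true(all(s$y %in% c(0, 1)))
  # law-of-large-numbers check on the uniform base variable
  s <- sample_functional(dependence_spec("quadratic", sigma = 0.1), 1e5,
                         seed = 4)
  expect_equal(mean(s$x), 0.5, tolerance = 0.01)
  expect_equal(var(s$x), 1 / 12, tolerance = 0.01)
  # determinism
  s1 <- sample_functional(dependence_spec("cubic", sigma = 0.2), 30, seed = 9)
  s2 <- sample_functional(dependence_spec("cubic", sigma = 0.2), 30, seed = 9)
  expect_identical(s1, s2)
  expect_error(dependence_spec("nope", sigma = 1), "arg")
  expect_error(dependence_spec("linear"), "sigma")
})

test_that("grid densities are normalized and reproduce known MI values", {
  gd <- grid_density(dependence_spec("linear", sigma = 0.2), m = 150)
  expect_equal(sum(gd$q), 1, tolerance = 1e-8)
  # pure noise: product density, zero MI
  gd0 <- grid_density(dependence_spec("independent", sigma = 0.7), m = 100)
  expect_lt(mutual_information_grid(gd0), 1e-10)
  # diagonal one-cell-per-row density has MI log(m)
  diag_cop <- patchwork_build(8, diag(8))
  expect_equal(mutual_information_grid(grid_density(
    dependence_spec("patchwork", copula = diag_cop), m = 8)), log(8),
    tolerance = 1e-12)
  # resolution convergence: linear, sigma = 0.2
  mi1 <- mutual_information_grid(grid_density(
    dependence_spec("linear", sigma = 0.2), m = 200))
  mi2 <- mutual_information_grid(grid_density(
    dependence_spec("linear", sigma = 0.2), m = 400))
  expect_lt(abs(mi1 - mi2) / mi2, 0.02)
})

test_that("sigma calibration hits its MI target and is monotone", {
  sg3 <- calibrate_sigma("linear", 0.3, tol = 0.005, m = 200)
  expect_lte(abs(attr(sg3, "mi") - 0.3), 0.005)
  mi_check <- mutual_information_grid(grid_density(
    dependence_spec("linear", sigma = as.numeric(sg3)), m = 200))
  expect_lte(abs(mi_check - 0.3), 0.005)
  sg05 <- calibrate_sigma("linear", 0.05, tol = 0.005, m = 200)
  expect_gt(as.numeric(sg05), as.numeric(sg3)) # more noise, less MI
  expect_error(calibrate_sigma("linear", -1), "target_mi")
})

test_that("patchwork copulas have uniform marginals and closed-form MI", {
  flat <- patchwork_build(1, 1)
  expect_equal(flat$mi, 0)
  diag2 <- patchwork_build(2, matrix(c(0.5, 0, 0, 0.5), 2))
  expect_equal(diag2$mi, log(2))
  expect_error(patchwork_build(2, matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
  expect_error(patchwork_build(2, matrix(0, 2, 2)), "all zero")
  set.seed(10)
  cop <- patchwork_build(4, runif(16))
  # breakpoints are the cumulative marginals
  expect_equal(cop$x_breaks, c(0, cumsum(rowSums(cop$p))))
  expect_equal(sum(cop$p), 1)
  # closed form equals the discretized MI on the refined grid
  gd <- grid_density(dependence_spec("patchwork", copula = cop), m = 64)
  expect_lt(abs(mutual_information_grid(gd) - cop$mi), 1e-10)
})

test_that("patchwork search reaches attainable targets and fails loudly otherwise", {
  cop <- patchwork_search(4, target_mi = 0.1, tol = 0.01, seed = 5)
  expect_lte(abs(cop$mi - 0.1), 0.01)
  expect_true(attr(cop, "n_proposals") >= 1)
  # near-zero target accepted by near-uniform weights
  cop0 <- patchwork_search(3, target_mi = 0.02, tol = 0.02, seed = 6)
  expect_lte(abs(cop0$mi - 0.02), 0.02)
  expect_error(patchwork_search(4, target_mi = log(4)), "not attainable")
  expect_error(
    patchwork_search(4, target_mi = log(4) - 1e-4, tol = 1e-6, seed = 1,
                     max_proposals = 50),
    "best")
})

test_that("patchwork samples land in their rectangles with the right frequencies", {
  diag2 <- patchwork_build(2, matrix(c(0.5, 0, 0, 0.5), 2))
  s <- patchwork_sample(diag2, 500, seed = 2)
  in_block <- (s$x <= 0.5 & s$y <= 0.5) | (s$x > 0.5 & s$y > 0.5)
  expect_true(all(in_block))
  flat <- patchwork_build(1, 1)
  s <- patchwork_sample(flat, 5000, seed = 3)
  expect_gt(suppressWarnings(ks.test(s$x, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(s$y, "punif"))$p.value, 0.01)
  # empirical cell frequencies match the weights (multinomial error)
  set.seed(11)
  cop <- patchwork_build(3, runif(9))
  s <- patchwork_sample(cop, 20000, seed = 4)
  i <- findInterval(s$x, cop$x_breaks, rightmost.closed = TRUE)
  j <- findInterval(s$y, cop$y_breaks, rightmost.closed = TRUE)
  emp <- table(factor(i, 1:3), factor(j, 1:3)) / 20000
  se <- sqrt(cop$p * (1 - cop$p) / 20000)
  expect_true(all(abs(emp - cop$p) <= 5 * pmax(se, 1e-4)))
})

test_that("torus projection tags samples without changing them", {
  s <- patchwork_sample(patchwork_build(1, 1), 100, seed = 1)
  tagged <- project_to_torus(s$x, s$y)
  expect_identical(tagged$x, s$x)
  expect_identical(tagged$geometry, "torus")
  expect_error(project_to_torus(c(-0.2, 0.5), c(0.1, 0.4)), "unit-square")
})

test_that("evaluate_method returns finite statistics and fails explicitly when a backend is missing", {
  set.seed(12)
  x <- runif(60); y <- runif(60)
  expect_equal(evaluate_method("pearson", x, x), 1)
  expect_true(is.finite(evaluate_method("pearson", x, y)))
  st <- evaluate_method("novel_ext", x, y, options = list(i_max = 10))
  expect_true(is.finite(st))
  expect_identical(st, evaluate_method("novel_ext", x, y,
                                       options = list(i_max = 10)))
  expect_true(is.finite(evaluate_method("novel_chisq", x, y,
                                        options = list(i_max = 10))))
  # kraskov_mi needs a user-supplied estimator
  expect_error(evaluate_method("kraskov_mi", x, y), "unavailable")
  expect_equal(evaluate_method("kraskov_mi", x, y,
                               options = list(estimator = function(a, b) 0.5)),
               0.5)
  for (m in c("dcor", "hoeffd", "mic")) {
    pkg <- c(dcor = "energy", hoeffd = "Hmisc", mic = "minerva")[[m]]
    if (requireNamespace(pkg, quietly = TRUE)) {
      expect_true(is.finite(evaluate_method(m, x, y)))
    } else {
      expect_error(evaluate_method(m, x, y), "unavailable")
    }
  }
  expect_error(evaluate_method("pearson", x, c(y[-1], NA)), "complete")
})

test_that("the power harness is calibrated under the null and monotone in MI", {
  null_spec <- dependence_spec("independent", sigma = 1, target_mi = 0)
  pw0 <- estimate_power("pearson", null_spec, n_points = 100, n_test = 200,
                        n_ref = 200, seed = 2)
  # 99% binomial band around alpha = 0.05 at 200 test samples
  expect_gte(pw0$power, 3 / 200)
  expect_lte(pw0$power, 17 / 200)
  sg1 <- as.numeric(calibrate_sigma("linear", 0.1, m = 150))
  sg4 <- as.numeric(calibrate_sigma("linear", 0.4, m = 150))
  pw1 <- estimate_power("pearson", dependence_spec("linear", sigma = sg1,
                                                   target_mi = 0.1),
                        n_points = 100, n_test = 50, n_ref = 50, seed = 3)
  pw4 <- estimate_power("pearson", dependence_spec("linear", sigma = sg4,
                                                   target_mi = 0.4),
                        n_points = 100, n_test = 50, n_ref = 50, seed = 3)
  expect_gte(pw4$power + 0.1, pw1$power) # monotone up to Monte-Carlo slack
  expect_gt(pw4$power, 0.9)             # strong linear signal is caught
})

test_that("ROC curves are monotone staircases with the right endpoints", {
  spec <- dependence_spec("linear", sigma = 0.1, target_mi = NULL)
  roc <- roc_points("pearson", spec, n_points = 50, n_test = 30, n_ref = 30,
                    seed = 4)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  expect_gte(auc, 0.5)
  # perfectly separated statistics pass through (0, 1)
  expect_true(any(roc$tpr == 1 & roc$fpr == 0) || auc < 1)
})
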