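test_that("m-set construction matches the closed-form sizes", {
  sets110 <- build_m_sets(110)
  expect_equal(length(sets110), 10)
  expect_equal(length(sets110[[1]]), 111)   # M_min = 55
  expect_equal(length(sets110[[10]]), 221)  # M = 110
  sets4 <- build_m_sets(4, n_grid = 1, M_max = 2)
  expect_equal(sets4[[1]], -2:2)
  expect_error(build_m_sets(10, M_max = 3), "M_min")
})

test_that("regression dimensions follow the block bookkeeping", {
  set.seed(11)
  vals <- matrix(runif(10), 5, 2,
                 dimnames = list(NULL, c("o1.g1", "o1.g2")))
  pr <- matrix_profile_set(c(4, 6, 8, 12, 16), vals)
  sys <- build_regression_system(pr, "disease", -2:2)
  expect_equal(dim(sys$X), c(5, 2))
  expect_equal(dim(sys$Y), c(5, 2))
  bd <- block_diagonal_system(sys)
  expect_equal(length(bd$y), 10)
  expect_equal(dim(bd$X), c(10, 4))
  # off-block entries are structural zeros
  expect_true(all(bd$X[1:5, 3:4] == 0))
  expect_true(all(bd$X[6:10, 1:2] == 0))
  expect_error(build_regression_system(pr, "disease", -0:0),
               "underdetermined")
})

test_that("a sinusoidal profile reproduces its analytic Hartley integrals", {
  # E(t) = sin(w0 t): H(w0) = T/2, H(-w0) = -T/2, other integer modes 0
  times <- seq(4, 16, length.out = 2001)
  spec <- hmf_spec(12)
  vals <- matrix(sin(spec$omega0 * (times - 4)), ncol = 1,
                 dimnames = list(NULL, "o1.g1"))
  pr <- matrix_profile_set(times, vals)
  sys <- build_regression_system(pr, "disease", -3:3)
  # column entries are Hbar(m w0) = H((1+m)w0) - H(m w0)
  hbar <- function(m) {
    h <- function(k) if (k == 1) 6 else if (k == -1) -6 else 0
    h(1 + m) - h(m)
  }
  for (mi in seq(-3, 3)) {
    if (mi %in% c(-1, 0)) next  # eps-substituted terms differ by design
    expect_equal(unname(sys$X[mi + 4, 1]), hbar(mi), tolerance = 1e-3)
  }
})

test_that("the solver is exact at lambda = 0 and empty at lambda_max", {
  set.seed(12)
  X <- matrix(rnorm(25), 5, 5)
  beta_star <- c(1, -2, 0.5, 0, 3)
  sys <- structure(list(X = X, Y = cbind(X %*% beta_star),
                        nodes = "o1.g1", m_set = 1:5),
                   class = "hmf_regression_system")
  K0 <- solve_block(X, sys$Y[, 1], alpha = 0.5, lambdas = 0)
  expect_equal(as.vector(K0), beta_star, tolerance = 1e-8)
  for (alpha in c(0.2, 1)) {
    lmax <- as.numeric(lambda_max(sys, alpha))
    expect_true(all(solve_block(X, sys$Y[, 1], alpha, lmax) == 0))
    # just below lambda_max the solution becomes nonzero
    expect_gt(sum(solve_block(X, sys$Y[, 1], alpha, lmax * 0.99) != 0), 0)
  }
})

test_that("lambda_max matches a brute-force bisection oracle", {
  set.seed(13)
  X <- matrix(rnorm(40), 8, 5)
  y <- rnorm(8)
  sys <- structure(list(X = X, Y = cbind(y), nodes = "n", m_set = 1:8),
                   class = "hmf_regression_system")
  for (alpha in c(0.3, 1)) {
    lo <- 1e-6; hi <- 1e6
    for (i in 1:60) {
      mid <- sqrt(lo * hi)
      if (all(solve_block(X, y, alpha, mid) == 0)) hi <- mid else lo <- mid
    }
    expect_equal(as.numeric(lambda_max(sys, alpha)), hi,
                 tolerance = 1e-5)
  }
})

test_that("lambda paths are log-spaced over four decades", {
  set.seed(14)
  X <- matrix(rnorm(30), 6, 5)
  sys <- structure(list(X = X, Y = cbind(rnorm(6)), nodes = "n",
                        m_set = 1:6),
                   class = "hmf_regression_system")
  path <- lambda_path(sys, 0.4, n_lambda = 10)
  ratios <- diff(log10(path))
  expect_equal(max(path) / min(path), 1e4, tolerance = 1e-8)
  expect_equal(ratios, rep(ratios[1], 9), tolerance = 1e-10)
})

test_that("univariate elastic net equals the soft-threshold closed form", {
  set.seed(15)
  x <- matrix(rnorm(20), ncol = 1)
  y <- rnorm(20)
  for (lambda in c(0.5, 2, 10)) for (alpha in c(0.3, 1)) {
    got <- solve_block(x, y, alpha, lambda)[1, 1]
    z <- sum(x * y)
    expected <- sign(z) * max(abs(z) - lambda * alpha / 2, 0) /
      (sum(x^2) + lambda * (1 - alpha))
    expect_equal(got, expected, tolerance = 1e-10)
    expect_equal(got, cd_elastic_net(x, y, lambda, alpha), tolerance = 1e-8)
  }
})

test_that("multivariate solutions agree with coordinate descent", {
  set.seed(16)
  X <- matrix(rnorm(60), 12, 5)
  y <- rnorm(12)
  obj <- function(b, lambda, alpha) {
    sum((y - X %*% b)^2) +
      lambda * (alpha * sum(abs(b)) + (1 - alpha) * sum(b^2))
  }
  for (alpha in c(0, 0.4, 1)) for (lambda in c(0.3, 3)) {
    got <- solve_block(X, y, alpha, lambda)[, 1]
    oracle <- cd_elastic_net(X, y, lambda, alpha, n_iter = 20000)
    # the two solvers approach the same optimum: coefficients to the
    # production solver's precision, objectives to relative 5e-5
    expect_lt(max(abs(got - oracle)), 5e-3)
    expect_equal(obj(got, lambda, alpha), obj(oracle, lambda, alpha),
                 tolerance = 5e-5)
  }
})

test_that("global block-diagonal and per-block solutions coincide", {
  set.seed(17)
  vals <- matrix(runif(15), 5, 3,
                 dimnames = list(NULL, c("o1.g1", "o1.g2", "o1.g3")))
  pr <- matrix_profile_set(c(4, 6, 8, 12, 16), vals)
  sys <- build_regression_system(pr, "disease", -3:3)
  K <- elastic_net_solve(sys, lambda = 0.7, alpha = 1)
  bd <- block_diagonal_system(sys)
  beta_global <- cd_elastic_net(bd$X, bd$y, 0.7, 1, n_iter = 20000)
  expect_equal(as.vector(t(K)), beta_global, tolerance = 1e-6)
})

test_that("the simulation objective evaluates the variance-penalized form", {
  # 2 nodes, dE2/dt = E1: yhat_2 = (0, 1), data (0, 0), sample var 0.5
  K <- matrix(c(0, 1, 0, 0), 2, 2,
              dimnames = list(c("o.a", "o.b"), c("o.a", "o.b")))
  vals <- matrix(c(1, 1, 0, 0), 2, 2,
                 dimnames = list(NULL, c("o.a", "o.b")))
  pr <- matrix_profile_set(c(0, 1), vals)
  sc <- simulate_and_score(K, pr, "disease")
  expect_equal(sc$j_sim, 1 / 0.5, tolerance = 1e-4)
  # perfect fit scores ~0
  K2 <- matrix(-1, 1, 1, dimnames = list("o.a", "o.a"))
  pr2 <- matrix_profile_set(c(0, 1, 2), matrix(exp(-c(0, 1, 2)),
                                               dimnames = list(NULL, "o.a")))
  expect_lt(simulate_and_score(K2, pr2, "disease")$j_sim, 1e-10)
})

test_that("the all-zero model is astronomically penalized", {
  set.seed(18)
  m <- generate_network(2, 3, 0.15, seed = 18)
  pr <- truth_profile_set(simulate_truth(m))
  K0 <- matrix(0, 6, 6, dimnames = list(m$nodes, m$nodes))
  expect_gt(simulate_and_score(K0, pr, "disease")$j_sim, 1e8)
})

test_that("grid search enumerates the full grid and beats the null model", {
  set.seed(19)
  m <- generate_network(2, 3, 0.15, seed = 19)
  pr <- truth_profile_set(simulate_truth(m))
  fit <- grid_search_identify(pr, "disease", alpha_grid = c(0.2, 1),
                              n_lambda = 4, n_m_sets = 2,
                              keep_models = "all")
  expect_equal(nrow(fit$fits), 2 * 2 * 4)
  expect_equal(length(fit$models), nrow(fit$fits))
  null_j <- simulate_and_score(matrix(0, 6, 6,
                                      dimnames = list(m$nodes, m$nodes)),
                               pr, "disease")$j_sim
  expect_lt(fit$best$j_sim, null_j)
})

test_that("subset restriction shrinks the system and still completes", {
  m <- generate_network(3, 2, 0.1, seed = 20)
  pr <- truth_profile_set(simulate_truth(m))
  fit <- grid_search_identify(pr, "disease", alpha_grid = 0.2,
                              n_lambda = 3, n_m_sets = 1,
                              subset_organs = c("organ01", "organ02"))
  expect_equal(length(fit$nodes), 4)
  expect_true(all(grepl("organ0[12]", fit$nodes)))
})

test_that("noise-free densely sampled dynamics are recovered exactly", {
  # self-consistency: with dense sampling the interpolant error vanishes
  # and small-lambda solutions recover K to high accuracy
  m <- generate_network(2, 3, 0.2, seed = 21)
  tr <- simulate_truth(m, times = seq(4, 16, by = 0.25))
  pr <- truth_profile_set(tr)
  sys <- build_regression_system(pr, "disease", -7:7)
  K <- elastic_net_solve(sys, lambda = 0, alpha = 0.2)
  expect_lt(max(abs(K - m$K_true)), 2e-2)
  supp <- m$K_true != 0
  expect_equal(sign(K[supp]), sign(m$K_true[supp]))
})

test_that("coefficients map back to the expression scale by profile ranges", {
  # k_ij on the expression scale is k_scaled,ij * range_i / range_j; check
  # the algebra against a hand-built profile set with known ranges
  nodes <- c("o.a", "o.b", "o.c")
  K_sc <- matrix(c(-1, 0.5, 0, 0.2, -2, 1, 0, 0, -3), 3, 3, byrow = TRUE,
                 dimnames = list(nodes, nodes))
  pr <- data.frame(strain = "disease",
                   organ = "o", gene = rep(c("a", "b", "c"), each = 2),
                   age_weeks = rep(c(4, 16), 3),
                   mean = c(0, 2, 1, 5, 3, 3.5), n_rep = 1)
  class(pr) <- c("profile_set", "data.frame")
  pr <- scale_profiles(pr)
  K <- unscale_coefficients(K_sc, pr, "disease")
  rng <- c(2, 4, 0.5)
  expect_equal(unname(K), unname(K_sc * outer(rng, 1 / rng)))
  # with strongly decaying dynamics the profile minima are ~0 so the
  # min-subtraction offset is negligible and the scaled-then-unscaled
  # identification approximates the truth
  m <- generate_network(1, 3, 0.3, coeff_scale = 0.6, seed = 22)
  tr <- simulate_truth(m, times = seq(4, 16, by = 0.25))
  prs <- scale_profiles(mean_profiles(data.frame(
    animal = "x", strain = "disease", organ = tr$organ, gene = tr$gene,
    age_weeks = tr$age_weeks, value = tr$value
  )))
  sys <- build_regression_system(prs, "disease", -7:7)
  K_hat <- unscale_coefficients(elastic_net_solve(sys, 0, 1), prs, "disease")
  expect_equal(sign(K_hat[m$K_true != 0]), sign(m$K_true[m$K_true != 0]))
  expect_lt(max(abs(K_hat - m$K_true)) / max(abs(m$K_true)), 0.2)
})

test_that("near-optimal fits on clean data agree in coefficient sign", {
  m <- generate_network(3, 4, 0.25, seed = 23)
  pr <- truth_profile_set(simulate_truth(m))
  fit <- grid_search_identify(pr, "disease", alpha_grid = c(0.2, 1),
                              n_lambda = 5, n_m_sets = 2,
                              keep_models = "all")
  near <- setdiff(which(fit$fits$j_sim < fit$best$j_sim * 10),
                  which.min(fit$fits$j_sim))
  cmp <- compare_network_batch(fit$best$K,
                               setNames(fit$models[near],
                                        paste0("f", near)))
  ok <- cmp[cmp$comparable, ]
  expect_gt(nrow(ok), 0)
  expect_true(all(is.infinite(ok$odds_ratio) | ok$odds_ratio > 1))
})
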