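test_that("theta update is exact eigenvalue soft-thresholding", {
  set.seed(1)
  R <- matrix(rnorm(36), 6, 6); R <- (R + t(R)) / 2

  # lambda1 = 0: identity
  expect_equal(unname(theta_update(R, 0, 3)), R, ignore_attr = TRUE)

  # full shrinkage: threshold at/above the spectral radius
  lam <- 2 * 3 * max(abs(eigen(R, symmetric = TRUE)$values))
  expect_equal(unname(theta_update(R, lam, 3)), matrix(0, 6, 6),
               ignore_attr = TRUE)

  # diag(3, 1), n = 1, lambda1 = 2 -> eigenvalues {2, 0}
  Th <- theta_update(diag(c(3, 1)), 2, 1)
  expect_equal(sort(eigen(Th, symmetric = TRUE)$values), c(0, 2),
               tolerance = 1e-12)

  expect_error(theta_update(matrix(1:4, 2, 2), 1, 1), "symmetric")
})

test_that("theta update matches numerical minimization of its objective", {
  # oracle: optimize the scalar objective over symmetric 2x2 matrices
  # parameterized by (a, b, c); nuclear norm via eigenvalues only.
  Rbar <- diag(c(3, 1)); n <- 1; lambda1 <- 2
  obj <- function(par) {
    Th <- matrix(c(par[1], par[3], par[3], par[2]), 2, 2)
    n * sum((Th - Rbar)^2) +
      lambda1 * sum(abs(eigen(Th, symmetric = TRUE, only.values = TRUE)$values))
  }
  opt <- optim(c(0, 0, 0), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  Th_hat <- theta_update(Rbar, lambda1, n)
  expect_equal(obj(c(Th_hat[1, 1], Th_hat[2, 2], Th_hat[1, 2])), opt$value,
               tolerance = 1e-6)
})

test_that("block summary equals brute-force index enumeration", {
  # community of 2 nodes with edge 0.5 -> within mean 0.5, m = 2
  cp2 <- community_partition(c(a = "g", b = "g"))
  vals <- array(0, dim = c(1, 2, 2)); vals[1, 1, 2] <- vals[1, 2, 1] <- 0.5
  bs <- block_summary(vals, cp2)
  expect_equal(bs$means[1, 1], 0.5)
  expect_equal(bs$counts, 2)

  # constant off-diagonal c -> every block mean c
  inst <- make_instance(n = 1, p = 6, K = 2, q = 1, seed = 2)
  cvals <- array(0.3, dim = c(1, 6, 6))
  for (j in 1:6) cvals[1, j, j] <- 0
  bsc <- block_summary(cvals, inst$partition)
  expect_equal(unname(bsc$means[1, ]), rep(0.3, 3))

  # random 6-node, K = 2 instance vs index-loop oracle
  inst <- make_instance(n = 4, p = 6, K = 2, q = 1, seed = 3)
  bs6 <- block_summary(inst$A, inst$partition)
  expect_equal(unname(bs6$means),
               unname(oracle_block_means(inst$A$values, inst$comm)),
               tolerance = 1e-12)
  expect_equal(bs6$counts,
               c(3 * 2, 3 * 3, 3 * 2))  # sizes (3,3): within, between, within
})

test_that("gamma update obeys the lasso zero condition and the OLS limit", {
  inst <- make_instance(n = 8, p = 6, K = 2, q = 2, seed = 4)
  bs <- block_summary(inst$A, inst$partition)
  C <- crossprod(inst$Xs, bs$means)
  l2max <- 2 * max(abs(sweep(C, 2, bs$counts, "*")))

  g0 <- gamma_update(bs, inst$Xs, l2max * 1.0000001)
  expect_true(all(vapply(g0, function(G) all(G == 0), TRUE)))

  # at lambda2 slightly below the threshold, at least one entry activates
  g1 <- gamma_update(bs, inst$Xs, l2max / 2)
  expect_gt(sum(abs(unlist(g1))), 0)

  # lambda2 = 0, q = 1: per block the weighted least-squares slope
  inst1 <- make_instance(n = 10, p = 6, K = 2, q = 1, seed = 5)
  bs1 <- block_summary(inst1$A, inst1$partition)
  gols <- gamma_update(bs1, inst1$Xs, 0)
  x <- inst1$Xs[, 1]
  for (b in 1:3) {
    slope <- sum(x * bs1$means[, b]) / sum(x^2)
    expect_equal(gols[[1]][bs1$k1[b], bs1$k2[b]], slope, tolerance = 1e-9)
  }
})

test_that("gamma update solves the per-block weighted lasso (convex oracle)", {
  skip_if_not_installed("glmnet")
  # one block with m = 2, n = 4, q = 2, seed-fixed ybar and X, lambda2 = 0.5
  set.seed(6)
  n <- 4
  X <- scale(matrix(rnorm(n * 2), n, 2))
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  ybar <- rnorm(n)
  summ <- structure(list(means = matrix(ybar, ncol = 1), counts = 2,
                         k1 = 1L, k2 = 1L),
                    class = "msnr_block_summary")
  g <- gamma_update(summ, X, 0.5)[[1]][1, 1]
  # within-block gamma entry appears once in the matrix l1 norm, so the
  # tiny problem is exactly: min_g 2 * sum_i (ybar_i - x_i'g)^2 + 0.5 ||g||_1
  g_star <- oracle_weighted_lasso(ybar, X, m = 2, lambda2 = 0.5)
  summ_g <- gamma_update(summ, X, 0.5)[[1]]
  expect_equal(c(summ_g[1, 1], 0), c(g_star[1], 0), tolerance = 1e-6)
  # full 2-covariate comparison
  expect_equal(unname(diag(summ_g)[1]), g_star[1], tolerance = 1e-6)

  # multi-block random case at several penalties
  inst <- make_instance(n = 12, p = 8, K = 2, q = 2, seed = 7)
  bs <- block_summary(inst$A, inst$partition)
  for (lam in c(0.5, 2, 8)) {
    gs <- gamma_update(bs, inst$Xs, lam)
    for (b in seq_along(bs$counts)) {
      target <- oracle_weighted_lasso(bs$means[, b], inst$Xs, bs$counts[b],
                                      if (bs$k1[b] == bs$k2[b]) lam else lam)
      got <- vapply(gs, function(G) G[bs$k1[b], bs$k2[b]], 0)
      expect_equal(got, target, tolerance = 1e-5,
                   label = sprintf("block %d lambda %.2f", b, lam))
    }
  }
})

test_that("gamma update warns on uncentered X and errors on zero variance", {
  inst <- make_instance(n = 6, p = 6, K = 2, q = 1, seed = 8)
  bs <- block_summary(inst$A, inst$partition)
  expect_warning(gamma_update(bs, inst$Xs + 1, 1), "centered")
  expect_error(gamma_update(bs, matrix(0, 6, 1), 1), "zero-variance")
})

test_that("fully shrunk fit returns the null model", {
  inst <- make_instance(n = 6, p = 8, K = 2, q = 2, seed = 9)
  A <- inst$A
  lm <- lambda_max(A, inst$Xs, inst$partition)
  fit <- msnr(A, inst$Xs, inst$partition, lm[1] * 1.001, lm[2] * 1.001)
  expect_equal(max(abs(fit$theta)), 0)
  expect_equal(max(abs(unlist(fit$gammas))), 0)
  expect_equal(unname(tail(fit$diagnostics$objective_trajectory, 1)),
               sum(A$values^2), tolerance = 1e-10)
})

test_that("lambda_max marks the exact activation boundary", {
  inst <- make_instance(n = 6, p = 8, K = 2, q = 2, seed = 10)
  lm <- lambda_max(inst$A, inst$Xs, inst$partition)
  # at lambda2_max the first gamma update from zero is all zeros
  bs <- block_summary(inst$A, inst$partition)
  g_at <- gamma_update(bs, inst$Xs, lm["lambda2_max"] * (1 + 1e-10))
  expect_true(all(unlist(g_at) == 0))
  # at lambda1_max with gammas zero, theta update returns zero
  Abar <- apply(inst$A$values, c(2, 3), mean)
  th <- theta_update(Abar, lm["lambda1_max"] * (1 + 1e-10), n_subjects(inst$A))
  expect_equal(max(abs(th)), 0)
  # halving lambda2 produces at least one active coefficient
  fit <- msnr(inst$A, inst$Xs, inst$partition, lm[1], lm[2] / 2)
  expect_gt(sum(unlist(fit$gammas) != 0), 0)
})

test_that("noiseless data at zero penalties is fit exactly", {
  sim <- simulate_msnr(n = 20, p = 16, K = 2, d = 2, q = 2,
                       gamma_sparsity = 0.3, noise_sd = 0, seed = 1)
  fit <- msnr(sim$A, sim$X, sim$partition, 0, 0)
  final <- tail(fit$diagnostics$objective_trajectory, 1)
  expect_lt(final, 1e-6 * sum(sim$A$values^2))
})

test_that("objective trajectory is monotone, finite, and correctly shaped", {
  for (seed in 1:30) {
    inst <- make_instance(n = sample(3:8, 1), p = sample(5:10, 1),
                          K = sample(2:3, 1), q = sample(1:2, 1), seed = seed)
    lm <- lambda_max(inst$A, inst$Xs, inst$partition)
    fit <- msnr(inst$A, inst$Xs, inst$partition,
                runif(1) * lm[1], runif(1) * lm[2])
    traj <- fit$diagnostics$objective_trajectory
    expect_true(all(is.finite(traj)))
    expect_true(all(diff(traj) <= 1e-8 * pmax(1, traj[-length(traj)])))
    expect_length(traj, fit$diagnostics$n_iterations + 1)
    expect_true(fit$diagnostics$converged)
    expect_symmetric(fit$theta)
    for (G in fit$gammas) expect_symmetric(G)
  }
})

test_that("solver matches the internal sufficient-statistic objective", {
  # the fast block-statistic objective evaluation inside the solver equals
  # a direct entry-by-entry recomputation (including the diagonal ridge)
  inst <- make_instance(n = 4, p = 7, K = 3, q = 2, seed = 11)
  fit <- msnr(inst$A, inst$Xs, inst$partition, 2, 1.5)
  direct <- oracle_objective_internal(fit$theta, fit$gammas, inst$A$values,
                                      inst$Xs, inst$partition$membership,
                                      2, 1.5)
  expect_equal(tail(fit$diagnostics$objective_trajectory, 1), direct,
               tolerance = 1e-10)
})

test_that("active-set size is monotone along the lambda2 path", {
  inst <- make_instance(n = 8, p = 10, K = 3, q = 2, seed = 12)
  lm <- lambda_max(inst$A, inst$Xs, inst$partition)
  path <- exp(seq(log(lm[2] * 1e-3), log(lm[2]), length.out = 10))
  nnz <- vapply(path, function(l2) {
    fit <- msnr(inst$A, inst$Xs, inst$partition, lm[1] / 10, l2)
    sum(unlist(fit$gammas) != 0)
  }, 0)
  expect_true(all(diff(nnz) <= 0))
})

test_that("support and sign of gamma are recovered at oracle penalties", {
  sim <- simulate_msnr(n = 100, p = 30, K = 3, d = 2, q = 2,
                       gamma_sparsity = 0.5, effect_size = 0.5,
                       noise_sd = 0.5, seed = 21)
  lm <- lambda_max(sim$A, standardize_covariates(sim$X), sim$partition)
  fit <- msnr(sim$A, sim$X, sim$partition, lm[1] * 0.05, lm[2] * 0.02)
  g_true <- unlist(sim$truth$gammas_true)
  g_hat <- unlist(fit$gammas)
  support <- g_true != 0
  expect_gte(mean(sign(g_hat[support]) == sign(g_true[support])), 0.9)
  expect_gte(cor(g_true, g_hat), 0.9)
})

test_that("non-convergence yields a warning and converged = FALSE", {
  inst <- make_instance(n = 4, p = 6, K = 2, q = 1, seed = 13)
  expect_warning(
    fit <- msnr(inst$A, inst$Xs, inst$partition, 1, 1,
                control = msnr_control(tol = 1e-30, max_iter = 1)),
    "converge")
  expect_false(fit$diagnostics$converged)
  expect_equal(fit$diagnostics$n_iterations, 1)
})

test_that("trace diagnostic reports Tr(W' theta W)", {
  inst <- make_instance(n = 5, p = 6, K = 2, q = 1, seed = 14)
  fit <- msnr(inst$A, inst$Xs, inst$partition, 0.5, 0.5)
  W <- inst$partition$membership
  expect_equal(fit$diagnostics$trace_WtThetaW,
               sum(diag(t(W) %*% fit$theta %*% W)), tolerance = 1e-10)
})
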