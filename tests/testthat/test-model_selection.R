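test_that("prediction error averages per-subject squared Frobenius norms", {
  inst <- make_instance(n = 3, p = 5, K = 2, q = 1, seed = 1)
  # perfect predictions -> 0
  expect_equal(stack_prediction_error(inst$A, inst$A$values), 0)

  # null model on one subject with constant off-diagonal c -> c^2 p (p-1)
  p <- 5; cval <- 0.4
  M <- matrix(cval, p, p); diag(M) <- 0
  A1 <- adjacency_stack(array(M, dim = c(1, p, p)))
  expect_equal(stack_prediction_error(A1, array(0, dim = c(1, p, p))),
               cval^2 * p * (p - 1))

  # averaging contract: two subjects with individual errors E1, E2
  A2 <- inst$A[1:2]
  P <- array(0, dim = dim(A2$values))
  E1 <- sum(A2$values[1, , ]^2); E2 <- sum(A2$values[2, , ]^2)
  expect_equal(stack_prediction_error(A2, P), (E1 + E2) / 2)

  expect_error(stack_prediction_error(A2, array(0, dim = c(1, 5, 5))),
               "dimension")
})

test_that("model prediction error standardizes test X with training stats", {
  sim <- simulate_msnr(n = 30, p = 12, K = 2, d = 2, q = 2, seed = 2)
  fit <- msnr(sim$A[1:20], sim$X[1:20], sim$partition, 1, 1)
  err <- prediction_error(fit, sim$A[21:30], sim$X[21:30])
  # manual recomputation through the shared routine
  Xs <- apply_standardization(sim$X[21:30], fit$center, fit$scale)$centered_scaled
  preds <- array(0, dim = c(10, 12, 12))
  for (i in 1:10) preds[i, , ] <- predict(fit, Xs[i, ])
  expect_equal(err, stack_prediction_error(sim$A[21:30], preds))
})

test_that("make_split is reproducible, disjoint and exhaustive", {
  s1 <- make_split(10, 0.2, seed = 5)
  expect_length(s1$validation, 2)
  expect_length(s1$train, 8)
  expect_setequal(c(s1$train, s1$validation), 1:10)
  expect_identical(s1, make_split(10, 0.2, seed = 5))
  s2 <- make_split(10, 0.2, seed = 6)
  expect_false(identical(s1$validation, s2$validation)) # a.s. for these seeds
  expect_error(make_split(3, 0.05), "too small")
})

test_that("cross-validation: shrinkage limit, argmin contract, determinism", {
  sim <- simulate_msnr(n = 30, p = 12, K = 3, d = 2, q = 2,
                       gamma_sparsity = 0.4, seed = 3)
  lm <- lambda_max(sim$A, standardize_covariates(sim$X), sim$partition)
  grid1 <- c(lm[1] / 10, lm[1] * 10)
  grid2 <- c(lm[2] / 10, lm[2] * 10)
  cv <- cross_validate(sim$A, sim$X, sim$partition, grid1, grid2,
                       n_folds = 3, seed = 11)
  # huge-penalty cell equals the null-model CV error (fully shrunk fits)
  null_err <- 0
  folds <- cv$fold_assignment
  for (f in 1:3) {
    te <- which(folds == f)
    null_err <- null_err + sum(sim$A$values[te, , , drop = FALSE]^2) / length(te)
  }
  expect_equal(cv$error_matrix[2, 2], null_err / 3, tolerance = 1e-10)
  # best indexes the minimal cell
  expect_equal(min(cv$error_matrix),
               cv$error_matrix[match(cv$best["lambda1"], cv$grid1),
                               match(cv$best["lambda2"], cv$grid2)])
  # determinism: identical seeds give identical results
  cv2 <- cross_validate(sim$A, sim$X, sim$partition, grid1, grid2,
                        n_folds = 3, seed = 11)
  expect_identical(cv$error_matrix, cv2$error_matrix)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
})

test_that("CV ties break toward the most regularized cell", {
  errs <- matrix(1, 2, 2)
  expect_equal(unname(msnr:::cv_argmin(errs, c(0.1, 1), c(0.2, 2))), c(1, 2))
  errs2 <- matrix(c(5, 1, 1, 5), 2, 2)   # ties at (2,1) and (1,2)
  expect_equal(unname(msnr:::cv_argmin(errs2, c(0.1, 1), c(0.2, 2))), c(1, 0.2))
})

test_that("CV-selected lambda2 is interior on sparse-signal data", {
  sim <- simulate_msnr(n = 40, p = 18, K = 3, d = 2, q = 2,
                       gamma_sparsity = 0.5, effect_size = 0.6,
                       noise_sd = 0.5, seed = 4)
  tune <- msnr_tune(sim$A, sim$X, sim$partition, n_folds = 4,
                    grid_points = 6, refine_rounds = 0, seed = 7)
  lm <- lambda_max(sim$A, standardize_covariates(sim$X), sim$partition)
  expect_gt(tune$best["lambda2"], 0)
  expect_lt(tune$best["lambda2"], lm["lambda2_max"])
})

test_that("grid refinement brackets the argmin and flags boundary hits", {
  cv <- structure(list(grid1 = c(1, 2, 4, 8), grid2 = c(1, 2, 4, 8),
                       error_matrix = matrix(0, 4, 4),
                       best = c(lambda1 = 2, lambda2 = 8),
                       refinement_round = 0L, seed = 1),
                  class = "msnr_cv")
  expect_warning(g <- refine_grid(cv), "upper edge")
  expect_equal(range(g$grid1), c(1, 4))       # interior: (prev, next)
  expect_equal(range(g$grid2), c(4, 16))      # edge: one octave beyond
  expect_true(2 %in% g$grid1)                 # argmin kept in refined grid
  expect_true(8 %in% g$grid2)

  # refined argmin error is no worse than the coarse argmin on same folds
  sim <- simulate_msnr(n = 30, p = 12, K = 2, d = 2, q = 2,
                       gamma_sparsity = 0.5, seed = 5)
  suppressWarnings(
    tune <- msnr_tune(sim$A, sim$X, sim$partition, n_folds = 3,
                      grid_points = 4, refine_rounds = 1, seed = 9))
  expect_lte(min(tune$rounds[[2]]$error_matrix),
             min(tune$rounds[[1]]$error_matrix) + 1e-12)
})

test_that("repeated splits report every repetition and their mean", {
  sim <- simulate_msnr(n = 25, p = 10, K = 2, d = 2, q = 1, seed = 10)
  suppressWarnings(
    rep2 <- msnr_repeated_splits(sim$A, sim$X, sim$partition, n_repeats = 2,
                                 n_folds = 3, grid_points = 3,
                                 refine_rounds = 0, seed = 4))
  expect_length(rep2$repeats, 2)
  expect_equal(rep2$mean_error, mean(rep2$validation_errors))
  expect_false(identical(rep2$repeats[[1]]$split, rep2$repeats[[2]]$split))
  # deterministic given the seed
  suppressWarnings(
    rep2b <- msnr_repeated_splits(sim$A, sim$X, sim$partition, n_repeats = 2,
                                  n_folds = 3, grid_points = 3,
                                  refine_rounds = 0, seed = 4))
  expect_identical(rep2$validation_errors, rep2b$validation_errors)
})

test_that("permutation p-value implements the proportion definition", {
  expect_equal(permutation_pvalue(c(2, 3, 4), 1), 0)
  expect_equal(permutation_pvalue(c(0.1, 0.2, 0.3), 1), 1)
  null <- c(rep(0.5, 250), rep(2, 750))
  expect_equal(permutation_pvalue(null, 1), 0.25)
  expect_error(permutation_pvalue(numeric(0), 1), "empty")
})

test_that("identity permutation reproduces the observed error exactly", {
  sim <- simulate_msnr(n = 24, p = 10, K = 2, d = 2, q = 2, seed = 6)
  split <- make_split(24, 0.25, seed = 1)
  tune_args <- list(n_folds = 3, grid_points = 3, refine_rounds = 0, seed = 2)
  run <- function(X) {
    tune <- do.call(msnr_tune, c(list(sim$A[split$train], X[split$train],
                                      sim$partition), tune_args))
    prediction_error(tune$fit, sim$A[split$validation], X[split$validation])
  }
  expect_equal(run(sim$X), run(sim$X[1:24]))
})

test_that("permutation test is deterministic and correctly assembled", {
  sim <- simulate_msnr(n = 24, p = 10, K = 2, d = 2, q = 2,
                       gamma_sparsity = 0.4, effect_size = 0.8,
                       noise_sd = 0.3, seed = 7)
  split <- make_split(24, 0.25, seed = 3)
  pt <- permutation_test(sim$A, sim$X, sim$partition, split, n_perm = 5,
                         seed = 4, n_folds = 3, grid_points = 3,
                         refine_rounds = 0)
  expect_length(pt$null_errors, 5)
  expect_equal(pt$p_value, permutation_pvalue(pt$null_errors, pt$observed_error))
  expect_equal(pt$z_score,
               (pt$observed_error - mean(pt$null_errors)) / sd(pt$null_errors))
  pt2 <- permutation_test(sim$A, sim$X, sim$partition, split, n_perm = 5,
                          seed = 4, n_folds = 3, grid_points = 3,
                          refine_rounds = 0)
  expect_identical(pt$null_errors, pt2$null_errors)
  expect_identical(pt$observed_error, pt2$observed_error)
})

test_that("CV cells equal a from-scratch leakage-free recomputation", {
  # recompute one grid cell entirely through the exported path: standardize
  # on the in-fold training part, apply those statistics to the held-out
  # fold (never its own), fit, and score with the shared error routine. A
  # leaky implementation (statistics from all subjects) would not match:
  # the sentinel shift on held-out covariates changes all-subject means.
  sim <- simulate_msnr(n = 20, p = 10, K = 2, d = 2, q = 1, seed = 8)
  X_shift <- sim$X$raw
  X_shift[1:3, ] <- X_shift[1:3, ] + 50      # sentinel rows
  Xct <- covariate_table(X_shift)
  cv <- cross_validate(sim$A, Xct, sim$partition, 1.5, 0.8,
                       n_folds = 2, seed = 5)
  manual <- 0
  for (f in 1:2) {
    tr <- which(cv$fold_assignment != f)
    te <- which(cv$fold_assignment == f)
    fit <- msnr(sim$A[tr], Xct[tr], sim$partition, 1.5, 0.8)
    manual <- manual + prediction_error(fit, sim$A[te], Xct[te])
  }
  expect_equal(cv$error_matrix[1, 1], manual / 2, tolerance = 1e-9)
})
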