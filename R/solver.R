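#' Solver settings for multi-scale network regression
#'
#' @param tol relative objective-change threshold for the outer block
#'   coordinate descent: stop when
#'   `|obj_t - obj_{t-1}| / max(1, obj_{t-1}) < tol` (scale-free, robust
#'   near zero).
#' @param max_iter maximum outer iterations.
#' @param inner_tol convergence threshold (max absolute coefficient change)
#'   for the per-block lasso coordinate descent.
#' @param inner_max_iter maximum inner coordinate-descent sweeps per block.
#' @return a list of class `"msnr_control"`.
#' @export
msnr_control <- function(tol = 1e-6, max_iter = 200L,
                         inner_tol = 1e-8, inner_max_iter = 1000L) {
  stopifnot(tol > 0, max_iter >= 1, inner_tol > 0, inner_max_iter >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 inner_tol = inner_tol, inner_max_iter = as.integer(inner_max_iter)),
            class = "msnr_control")
}

#' Low-rank block update: eigenvalue soft-thresholding
#'
#' Exact minimizer of `n * ||Theta - Rbar||_F^2 + lambda1 * ||Theta||_*`
#' over symmetric `Theta`: eigendecompose `Rbar = U diag(d) U'` and shrink
#' each eigenvalue toward zero by `lambda1 / (2n)`, zeroing those with
#' absolute value at or below the threshold. For symmetric matrices the
#' nuclear norm equals the sum of absolute eigenvalues, so the symmetric
#' eigendecomposition is exact (and half the cost of a general SVD).
#'
#' @param Rbar symmetric `p x p` mean-residual matrix
#'   `(1/n) * sum_i (A^i - sum_f X_if W Gamma^f W')`.
#' @param lambda1 nonnegative nuclear-norm weight.
#' @param n number of subjects behind the average.
#' @return symmetric `p x p` matrix with attribute `"nuclear"` holding its
#'   nuclear norm.
#' @export
theta_update <- function(Rbar, lambda1, n) {
  Rbar <- as.matrix(Rbar)
  if (max(abs(Rbar - t(Rbar))) > 1e-8) stopf("`Rbar` must be symmetric")
  if (lambda1 < 0) stopf("lambda1 must be nonnegative")
  if (lambda1 == 0) {
    out <- Rbar
    attr(out, "nuclear") <- nuclear_norm_sym(Rbar)
    return(out)
  }
  eg <- eigen((Rbar + t(Rbar)) / 2, symmetric = TRUE)
  d <- soft_threshold(eg$values, lambda1 / (2 * n))
  keep <- d != 0
  out <- if (!any(keep)) {
    matrix(0, nrow(Rbar), ncol(Rbar))
  } else {
    U <- eg$vectors[, keep, drop = FALSE]
    U %*% (d[keep] * t(U))
  }
  out <- (out + t(out)) / 2
  attr(out, "nuclear") <- sum(abs(d))
  out
}

#' Per-subject community-block residual summary
#'
#' Reduces a residual stack to its sufficient statistics for the sparse
#' block update: for every subject `i` and unordered community pair
#' `(k <= k')`, the mean of the residual entries over that block's
#' off-diagonal positions, together with the block entry counts
#' `m_kk = |C_k|(|C_k| - 1)` (within) and `m_kk' = |C_k||C_k'|` (between,
#' one orientation). Singleton communities have `m_kk = 0`; their within
#' block is excluded from the loss and the corresponding `Gamma` diagonal
#' entries stay fixed at zero.
#'
#' @param residuals an [adjacency_stack()] or `n x p x p` array of
#'   symmetric residual matrices.
#' @param partition a [community_partition()].
#' @return object of class `"msnr_block_summary"`: `means` (`n x B` matrix,
#'   `B = K(K+1)/2`, blocks in lexicographic `(k, k')` order), `counts`
#'   (`m` per block), `k1`, `k2` (community indices per block).
#' @export
block_summary <- function(residuals, partition) {
  vals <- if (inherits(residuals, "adjacency_stack")) residuals$values else residuals
  stopifnot(inherits(partition, "community_partition"))
  n <- dim(vals)[1L]
  bp <- block_pairs(partition)
  means <- matrix(NA_real_, n, bp$n_blocks)
  for (i in seq_len(n)) {
    means[i, ] <- block_mean_vec(vals[i, , ], partition, bp)
  }
  structure(list(means = means, counts = bp$m, k1 = bp$k1, k2 = bp$k2),
            class = "msnr_block_summary")
}

# Block means (diagonal excluded) of one symmetric p x p matrix, as a
# length-B vector in lexicographic block order. Blocks with m = 0 get 0.
block_mean_vec <- function(M, partition, bp = block_pairs(partition)) {
  W <- partition$membership
  S <- crossprod(W, M %*% W)                       # K x K block sums (incl. diag)
  dsum <- as.vector(crossprod(W, diag(M)))         # per-community diagonal sums
  sums <- S[cbind(bp$k1, bp$k2)]
  within <- bp$k1 == bp$k2
  sums[within] <- sums[within] - dsum[bp$k1[within]]
  out <- numeric(length(sums))
  pos <- bp$m > 0
  out[pos] <- sums[pos] / bp$m[pos]
  out
}

#' Sparse block update: decoupled weighted lassos
#'
#' Given block-mean residual summaries, solves for each unordered community
#' pair `(k <= k')` independently
#' \deqn{\min_\gamma m_{kk'} \sum_i (\bar y^i_{kk'} - x_i^T \gamma)^2
#'       + \lambda_2 \|\gamma\|_1}
#' by cyclic coordinate descent with exact scalar soft-threshold updates,
#' and writes the solutions symmetrically into `q` matrices `Gamma^f`.
#' (The factor-2 double count of between blocks in both the loss and the
#' matrix l1 penalty cancels, so one weighted lasso per unordered pair with
#' weight `m_kk'` is exact; the test suite verifies this against a generic
#' convex-solver oracle.)
#'
#' @param summary an [block_summary()] of the residuals `A^i - Theta`.
#' @param X standardized `n x q` covariate matrix (column means ~ 0) or a
#'   standardized [covariate_table()].
#' @param lambda2 nonnegative l1 weight.
#' @param warm_start optional list of `q` `K x K` matrices to start from.
#' @param control an [msnr_control()].
#' @return list of `q` symmetric `K x K` matrices.
#' @export
gamma_update <- function(summary, X, lambda2, warm_start = NULL,
                         control = msnr_control()) {
  stopifnot(inherits(summary, "msnr_block_summary"))
  Xs <- resolve_standardized(X)
  if (lambda2 < 0) stopf("lambda2 must be nonnegative")
  xtx <- crossprod(Xs)
  if (any(diag(xtx) <= 0)) stopf("zero-variance covariate")
  if (max(abs(colMeans(Xs))) > 1e-6) {
    warnf("covariates do not appear to be centered; block updates assume standardized X")
  }
  K <- max(summary$k2)
  coef <- gamma_cd(summary$means, Xs, xtx, summary$counts, lambda2,
                   warm = if (is.null(warm_start)) NULL else
                     gamma_list_to_coef(warm_start, summary),
                   control = control)
  gamma_coef_to_list(coef, summary, K)
}

# Cyclic coordinate descent over blocks. means: n x B, coef returned B x q.
# Covariates are cycled in input order within each block; blocks are
# processed in lexicographic (k, k') order.
gamma_cd <- function(means, Xs, xtx, m, lambda2, warm = NULL, control = msnr_control()) {
  q <- ncol(Xs)
  B <- ncol(means)
  C <- crossprod(Xs, means)                 # q x B: sum_i x_if * ybar_ib
  coef <- if (is.null(warm)) matrix(0, B, q) else warm
  half <- lambda2 / 2
  dxtx <- diag(xtx)
  imax <- control$inner_max_iter
  itol <- control$inner_tol
  # blocks are mutually independent lassos, so the coordinate-f update can
  # be applied to every block simultaneously (identical to per-block cyclic
  # descent in the same covariate order, vectorized over blocks)
  active <- m > 0
  msafe <- pmax(m, 1)
  for (it in seq_len(imax)) {
    delta <- 0
    for (f in seq_len(q)) {
      rho <- C[f, ] - drop(coef %*% xtx[, f]) + dxtx[f] * coef[, f]
      z <- m * rho
      gf <- sign(z) * pmax(abs(z) - half, 0) / (msafe * dxtx[f])
      gf[!active] <- 0
      delta <- max(delta, abs(gf - coef[, f]))
      coef[, f] <- gf
    }
    if (delta < itol) break
  }
  coef[!active, ] <- 0
  coef
}

gamma_coef_to_list <- function(coef, summary, K) {
  q <- ncol(coef)
  lapply(seq_len(q), function(f) {
    G <- matrix(0, K, K)
    G[cbind(summary$k1, summary$k2)] <- coef[, f]
    G[cbind(summary$k2, summary$k1)] <- coef[, f]
    G
  })
}

gamma_list_to_coef <- function(gammas, summary) {
  vapply(gammas, function(G) G[cbind(summary$k1, summary$k2)],
         numeric(length(summary$k1)))
}

#' Smallest penalties that fully shrink the fit
#'
#' `lambda2_max` is the smallest `lambda2` at which the first sparse block
#' update from zero returns all zeros:
#' `max over (k <= k', f) of 2 * m_kk' * |sum_i x_if * ybar^i_kk'|`
#' evaluated at `Theta = 0`. `lambda1_max` is the smallest `lambda1` at
#' which the low-rank update returns zero when `Gamma = 0`:
#' `2n * max |eig(Abar)|` with `Abar` the subject-mean adjacency. Used to
#' build penalty grids for cross-validation.
#'
#' @param A an [adjacency_stack()].
#' @param X standardized covariates (`covariate_table` or matrix).
#' @param partition a [community_partition()].
#' @return named numeric vector `c(lambda1_max, lambda2_max)`.
#' @export
lambda_max <- function(A, X, partition) {
  Xs <- resolve_standardized(X)
  n <- n_subjects(A)
  bs <- block_summary(A, partition)
  C <- crossprod(Xs, bs$means)                       # q x B
  l2 <- 2 * max(abs(sweep(C, 2L, bs$counts, "*")))
  Abar <- apply(A$values, c(2L, 3L), mean)
  l1 <- 2 * n * max(abs(eigen(Abar, symmetric = TRUE, only.values = TRUE)$values))
  c(lambda1_max = l1, lambda2_max = l2)
}

#' Fit multi-scale network regression
#'
#' Solves the convex penalized problem
#' \deqn{\min_{\Theta, \Gamma^1..\Gamma^q}
#'   \sum_i \|A^i - \Theta - Z(\textstyle\sum_f X_{if} W \Gamma^f W^T)\|_F^2
#'   + \lambda_1 \|\Theta\|_* + \lambda_2 \sum_f \|\Gamma^f\|_1}
#' (`Z` zeroes the diagonal of the community term; `A^i` has zero diagonal)
#' by block coordinate descent from `Theta = 0`, `Gamma = 0`, alternating
#' the exact closed-form updates [gamma_update()] (residuals `A^i - Theta`)
#' and [theta_update()] (residuals `A^i - sum_f X_if W Gamma^f W'`) until
#' the relative objective change falls below `control$tol`. Both updates
#' are exact block minimizers of one convex objective, so the recorded
#' objective trajectory is non-increasing and the limit is a global
#' optimum. Covariates are standardized internally (training statistics are
#' stored on the model) unless an already-standardized table is supplied.
#'
#' @param A an [adjacency_stack()] (n >= 2 subjects).
#' @param X a [covariate_table()] (raw, or already standardized) or an
#'   `n x q` matrix of raw covariates.
#' @param partition a [community_partition()].
#' @param lambda1,lambda2 nonnegative penalty weights.
#' @param control an [msnr_control()].
#' @return a fitted [msnr_model()] whose `diagnostics` element holds
#'   `objective_trajectory` (length `n_iterations + 1`, starting from the
#'   all-zero model), `n_iterations`, `converged`,
#'   `final_relative_change`, and `trace_WtThetaW` (the identifiability
#'   diagnostic `Tr(W' Theta W)`, reported but not enforced).
#' @examples
#' sim <- simulate_msnr(n = 20, p = 12, K = 2, d = 2, q = 1, seed = 1)
#' fit <- msnr(sim$A, sim$X, sim$partition, lambda1 = 1, lambda2 = 1)
#' fit
#' @export
msnr <- function(A, X, partition, lambda1, lambda2, control = msnr_control()) {
  stopifnot(inherits(A, "adjacency_stack"), inherits(partition, "community_partition"))
  lambda1 <- as.numeric(lambda1)[1L]
  lambda2 <- as.numeric(lambda2)[1L]
  if (lambda1 < 0 || lambda2 < 0) stopf("penalties must be nonnegative")
  n <- n_subjects(A)
  if (n < 2) stopf("need at least 2 subjects")
  if (nrow(partition$membership) != n_nodes(A)) {
    stopf("partition has %d nodes, adjacency has %d",
          nrow(partition$membership), n_nodes(A))
  }
  if (!inherits(X, "covariate_table")) X <- covariate_table(X)
  if (!is_standardized(X)) X <- standardize_covariates(X)
  if (nrow(X$raw) != n) stopf("covariate rows (%d) != subjects (%d)", nrow(X$raw), n)

  pre <- msnr_precompute(A$values, partition)
  core <- msnr_core(pre, X$centered_scaled, lambda1, lambda2, control)
  W <- partition$membership
  diagnostics <- list(
    objective_trajectory = core$trajectory,
    n_iterations = core$n_iterations,
    converged = core$converged,
    final_relative_change = core$final_relative_change,
    trace_WtThetaW = sum(diag(crossprod(W, core$theta %*% W)))
  )
  if (!core$converged) {
    warnf("msnr did not converge in %d iterations (relative change %.3g)",
          core$n_iterations, core$final_relative_change)
  }
  msnr_model(core$theta, core$gammas, partition, lambda1, lambda2,
             center = X$center, scale = X$scale, diagnostics = diagnostics)
}

# ---- internal fast path -----------------------------------------------------
# Sufficient statistics of an adjacency stack for repeated fits (CV,
# permutations): per-subject block means, subject-mean matrix, total squared
# norm, and full-matrix block entry counts w (within: m, between: 2m).
msnr_precompute <- function(vals, partition) {
  n <- dim(vals)[1L]
  bp <- block_pairs(partition)
  bs <- block_summary(vals, partition)
  Abar <- apply(vals, c(2L, 3L), mean)
  list(partition = partition, bp = bp, means = bs$means,
       Abar = Abar, sumA2 = sum(vals^2), n = n,
       w = ifelse(bp$k1 == bp$k2, bp$m, 2 * bp$m))
}

# Block coordinate descent on the precomputed statistics. `eigA`: optional
# cached eigen(Abar) reused across penalty values when X is centered (the
# Theta subproblem then has constant mean residual Abar, exactly).
msnr_core <- function(pre, Xs, lambda1, lambda2, control = msnr_control(),
                      eigA = NULL) {
  n <- pre$n
  bp <- pre$bp
  q <- ncol(Xs)
  xtx <- crossprod(Xs)
  if (any(diag(xtx) <= 0)) stopf("zero-variance covariate")
  xbar <- colMeans(Xs)
  centered <- max(abs(xbar)) < 1e-10
  W <- pre$partition$membership

  theta <- matrix(0, nrow(W), nrow(W))
  theta_nuc <- 0
  theta_bm <- numeric(bp$n_blocks)           # block means of theta (diag excluded)
  theta_cross <- 0                            # n * <Abar, theta>  (off-diag only)
  theta_f2 <- 0                               # ||theta||_F^2 (incl. diagonal)
  coef <- matrix(0, bp$n_blocks, q)           # stacked block lasso coefficients

  # l1 over the full K x K matrices: diagonal blocks once, off-diagonal twice.
  wpen <- 2 - (bp$k1 == bp$k2)
  objective <- function() {
    # sum_i ||A_i - theta - Z(S_i)||_F^2 via block sufficient statistics;
    # S = Xs %*% t(coef) gives s_ib = x_i' gamma_b.
    S <- Xs %*% t(coef)
    loss <- pre$sumA2 - 2 * theta_cross + n * theta_f2 +
      sum(colSums(S * (S + rep(2 * theta_bm, each = n) - 2 * pre$means)) * pre$w)
    loss + lambda1 * theta_nuc + lambda2 * sum(abs(coef) * wpen)
  }

  traj <- objective()                        # all-zero start
  converged <- FALSE
  rel <- Inf
  iter <- 0L
  if (centered && is.null(eigA) && lambda1 > 0) {
    eigA <- eigen(pre$Abar, symmetric = TRUE)
  }

  for (iter in seq_len(control$max_iter)) {
    # Gamma half-step: residual block means are means(A) - blockmeans(theta)
    means_resid <- sweep(pre$means, 2L, theta_bm, "-")
    coef <- gamma_cd(means_resid, Xs, xtx, bp$m, lambda2, warm = coef,
                     control = control)
    # Theta half-step: mean residual Abar - Z(sum_f xbar_f W G^f W')
    if (centered) {
      if (lambda1 == 0) {
        theta <- pre$Abar
        theta_nuc <- nuclear_norm_sym(theta)
      } else {
        d <- soft_threshold(eigA$values, lambda1 / (2 * n))
        keep <- d != 0
        theta <- if (!any(keep)) matrix(0, nrow(W), nrow(W)) else {
          U <- eigA$vectors[, keep, drop = FALSE]
          U %*% (d[keep] * t(U))
        }
        theta <- (theta + t(theta)) / 2
        theta_nuc <- sum(abs(d))
      }
    } else {
      Rbar <- pre$Abar - zero_diag(expand_blocks(drop(coef %*% xbar), bp, W))
      theta <- theta_update(Rbar, lambda1, n)
      theta_nuc <- attr(theta, "nuclear")
      attr(theta, "nuclear") <- NULL
    }
    theta_bm <- block_mean_vec(theta, pre$partition, bp)
    theta_cross <- n * sum(pre$Abar * zero_diag(theta))
    theta_f2 <- frob2(theta)

    obj <- objective()
    prev <- utils::tail(traj, 1L)
    traj <- c(traj, obj)
    rel <- abs(obj - prev) / max(1, prev)
    if (rel < control$tol) { converged <- TRUE; break }
  }

  K <- n_communities(pre$partition)
  list(theta = theta,
       gammas = gamma_coef_to_list(coef, list(k1 = bp$k1, k2 = bp$k2), K),
       coef = coef,
       trajectory = traj, n_iterations = iter, converged = converged,
       final_relative_change = rel)
}

# Expand a per-block coefficient vector (length B, lexicographic) into the
# p x p matrix W G W' it represents.
expand_blocks <- function(blockvec, bp, W) {
  K <- ncol(W)
  G <- matrix(0, K, K)
  G[cbind(bp$k1, bp$k2)] <- blockvec
  G[cbind(bp$k2, bp$k1)] <- blockvec
  W %*% G %*% t(W)
}

# Held-out squared-Frobenius error per subject from sufficient statistics;
# equals mean_i ||A_i - Z(theta + S_i)||_F^2 (predicted diagonal zeroed).
pred_err_stats <- function(pre_test, Xs_test, theta, coef) {
  n <- pre_test$n
  bp <- pre_test$bp
  theta_off <- zero_diag(theta)
  theta_off2 <- frob2(theta_off)
  theta_cross <- sum(pre_test$Abar * theta_off)        # per-subject average
  theta_bm <- block_mean_vec(theta, pre_test$partition, bp)
  S <- Xs_test %*% t(coef)
  tot <- pre_test$sumA2 - 2 * n * theta_cross + n * theta_off2 +
    sum(colSums(S * (S + rep(2 * theta_bm, each = n) - 2 * pre_test$means)) *
          pre_test$w)
  tot / n
}
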