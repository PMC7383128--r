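#' @title The multi-scale network regression model
#'
#' @description
#' The model for subject `i`'s symmetric `p x p` connectivity matrix is
#' \deqn{A^i = \Theta + \sum_{f=1}^q X_{if} \, W \Gamma^f W^T + \epsilon^i,}
#' where `Theta` is a shared (ideally low-rank) mean connectivity matrix,
#' `W` is the `p x K` community indicator matrix, and each `Gamma^f` is a
#' symmetric (ideally sparse) `K x K` matrix of community-level covariate
#' effects: a one-unit increase in standardized covariate `f` shifts the
#' mean connectivity between communities `k` and `k'` by `Gamma^f[k, k']`.
#'
#' `msnr_model()` assembles a model object from its components (the fitted
#' counterpart is produced by [msnr()]); `predict()` evaluates the model's
#' systematic part for a covariate vector; `msnr_objective()` evaluates the
#' penalized least-squares criterion.
#'
#' @param theta symmetric `p x p` matrix.
#' @param gammas list of `q` symmetric `K x K` matrices.
#' @param partition a [community_partition()].
#' @param lambda1,lambda2 nonnegative penalty weights for the nuclear norm
#'   of `theta` and the elementwise l1 norm of the `gammas`.
#' @param center,scale optional covariate standardization statistics
#'   (length `q`) stored with a fitted model.
#' @param diagnostics optional fit diagnostics (see [msnr()]).
#' @return object of class `"msnr_model"`.
#' @export
msnr_model <- function(theta, gammas, partition, lambda1 = 0, lambda2 = 0,
                       center = NULL, scale = NULL, diagnostics = NULL) {
  stopifnot(inherits(partition, "community_partition"))
  theta <- as.matrix(theta)
  p <- nrow(partition$membership)
  K <- n_communities(partition)
  if (!isTRUE(all.equal(dim(theta), c(p, p)))) stopf("theta must be %d x %d", p, p)
  if (max(abs(theta - t(theta))) > 1e-8) stopf("theta must be symmetric")
  if (!is.list(gammas)) gammas <- list(gammas)
  for (f in seq_along(gammas)) {
    G <- as.matrix(gammas[[f]])
    if (!isTRUE(all.equal(dim(G), c(K, K)))) stopf("gamma %d must be %d x %d", f, K, K)
    if (max(abs(G - t(G))) > 1e-8) stopf("gamma %d must be symmetric", f)
    gammas[[f]] <- G
  }
  if (lambda1 < 0 || lambda2 < 0) stopf("penalties must be nonnegative")
  structure(
    list(theta = theta, gammas = gammas, partition = partition,
         lambda1 = lambda1, lambda2 = lambda2,
         center = center, scale = scale, diagnostics = diagnostics),
    class = "msnr_model"
  )
}

#' @export
print.msnr_model <- function(x, ...) {
  cat(sprintf("<msnr_model: p = %d, K = %d, q = %d, lambda1 = %.4g, lambda2 = %.4g>\n",
              nrow(x$theta), n_communities(x$partition), length(x$gammas),
              x$lambda1, x$lambda2))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  converged: %s after %d iterations (final objective %.6g)\n",
                x$diagnostics$converged, x$diagnostics$n_iterations,
                utils::tail(x$diagnostics$objective_trajectory, 1L)))
  }
  invisible(x)
}

#' Predict a connectivity matrix from covariates
#'
#' Evaluates `Theta + sum_f x_f W Gamma^f W^T` with the diagonal forced to
#' zero (the package's edge convention: self-connectivity is excluded from
#' the response and from predictions).
#'
#' @param object an `msnr_model`.
#' @param x numeric covariate vector of length `q`, **on the model's
#'   standardized scale**; use `newdata` with a raw-scale
#'   [covariate_table()] instead to have the model's stored training
#'   statistics applied.
#' @param newdata optional `covariate_table` (raw scale); returns one
#'   predicted matrix per subject as an `n x p x p` array.
#' @param ... unused.
#' @return a symmetric `p x p` matrix with zero diagonal (or an
#'   `n x p x p` array when `newdata` is given).
#' @export
predict.msnr_model <- function(object, x = NULL, newdata = NULL, ...) {
  W <- object$partition$membership
  q <- length(object$gammas)
  if (!is.null(newdata)) {
    stopifnot(inherits(newdata, "covariate_table"))
    if (is.null(object$center)) stopf("model carries no standardization statistics")
    Xs <- apply_standardization(newdata, object$center, object$scale)$centered_scaled
    p <- nrow(object$theta)
    out <- array(0, dim = c(nrow(Xs), p, p))
    for (i in seq_len(nrow(Xs))) out[i, , ] <- predict(object, Xs[i, ])
    return(out)
  }
  if (length(x) != q) stopf("covariate vector must have length %d", q)
  M <- object$theta
  for (f in seq_len(q)) {
    if (x[f] != 0) M <- M + x[f] * (W %*% object$gammas[[f]] %*% t(W))
  }
  zero_diag((M + t(M)) / 2)
}

#' Penalized least-squares objective
#'
#' Evaluates
#' \deqn{\sum_i \|A^i - \hat A^i(x_i)\|_F^2
#'       + \lambda_1 \|\Theta\|_* + \lambda_2 \sum_f \|\Gamma^f\|_1}
#' where the prediction `\hat A^i` has zero diagonal (so diagonal terms
#' contribute nothing to the loss), the nuclear norm of the symmetric
#' `Theta` is the sum of absolute eigenvalues, and the l1 norm sums `|.|`
#' over all `K^2` entries of each `Gamma^f`.
#'
#' Note: the solver's reported `objective_trajectory` additionally includes
#' an implicit `n * sum(diag(Theta)^2)` ridge term (see the package
#' vignette); the two agree whenever `diag(Theta) = 0`.
#'
#' @param model an `msnr_model` (its `lambda1`, `lambda2` are used).
#' @param A an [adjacency_stack()].
#' @param X a standardized [covariate_table()] (or a plain `n x q` matrix
#'   already on the standardized scale).
#' @return nonnegative scalar.
#' @export
msnr_objective <- function(model, A, X) {
  Xs <- resolve_standardized(X, length(model$gammas))
  vals <- A$values
  n <- dim(vals)[1L]
  if (nrow(Xs) != n) stopf("covariate rows (%d) != subjects (%d)", nrow(Xs), n)
  loss <- 0
  for (i in seq_len(n)) {
    loss <- loss + frob2(vals[i, , ] - predict(model, Xs[i, ]))
  }
  loss + model$lambda1 * nuclear_norm_sym(model$theta) +
    model$lambda2 * sum(vapply(model$gammas, function(G) sum(abs(G)), 0))
}

# Sum of absolute eigenvalues (= nuclear norm for symmetric matrices).
nuclear_norm_sym <- function(M) {
  sum(abs(eigen(M, symmetric = TRUE, only.values = TRUE)$values))
}

# Accept a standardized covariate_table or a bare matrix; return the matrix.
resolve_standardized <- function(X, q = NULL) {
  if (inherits(X, "covariate_table")) {
    if (!is_standardized(X)) stopf("covariate table must be standardized first")
    Xs <- X$centered_scaled
  } else {
    Xs <- as.matrix(X)
  }
  if (!is.null(q) && ncol(Xs) != q) stopf("expected %d covariates, got %d", q, ncol(Xs))
  Xs
}
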