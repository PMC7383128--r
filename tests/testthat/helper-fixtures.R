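# Small randomized fixtures, generated in code (no stored data).

# Random symmetric zero-diagonal stack + standardized covariates + a
# partition with K near-equal communities.
make_instance <- function(n = 5, p = 6, K = 2, q = 2, seed = 1) {
  set.seed(seed)
  vals <- array(0, dim = c(n, p, p))
  for (i in seq_len(n)) {
    M <- matrix(rnorm(p * p), p, p)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    vals[i, , ] <- M
  }
  A <- adjacency_stack(vals)
  X <- matrix(rnorm(n * q), n, q)
  X <- scale(X)
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  sizes <- diff(floor(seq(0, p, length.out = K + 1)))
  part <- community_partition(
    stats::setNames(rep(paste0("c", seq_len(K)), times = sizes), A$node_ids))
  list(A = A, Xs = X, partition = part,
       comm = apply(part$membership, 1, which.max))
}

expect_symmetric <- function(M, tol = 1e-12) {
  testthat::expect_lt(max(abs(M - t(M))), tol)
}

# access to the internal vectorized OLS for baseline convergence checks
ols_fit_multi_test <- function(Y, X) msnr:::ols_fit_multi(Y, X)

# minimal tempdir helper (auto-cleaned by testthat's temp handling)
withr_local_tempdir <- function() {
  d <- tempfile("msnr-test-")
  dir.create(d)
  d
}
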