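#' Simulate cohorts under the multi-scale generative model
#'
#' Generates `n` symmetric adjacency matrices from
#' `A^i = Theta* + sum_f X_if W Gamma*^f W' + eps^i` with known ground
#' truth, for solver validation, parameter recovery, cross-validation and
#' permutation calibration studies:
#'
#' * covariates `X`: i.i.d. standard normal entries, then column
#'   standardized (exact mean 0, sd 1);
#' * low-rank mean `Theta* = V V'` with `V` a `p x d` matrix of i.i.d.
#'   `N(0, theta_scale^2 / sqrt(d))` entries, so the nodes live in a
#'   `d`-dimensional latent space;
#' * sparse effects `Gamma*^f`: each upper-triangle entry (including the
#'   diagonal) is nonzero with probability `1 - gamma_sparsity`, taking
#'   value `effect_size` with a random sign, mirrored to symmetry;
#' * noise `eps^i`: symmetric with i.i.d. `N(0, noise_sd^2)` strict
#'   upper-triangle entries and zero diagonal.
#'
#' Nodes are split into `K` near-equal contiguous communities. All
#' diagonals are zeroed (the package's edge convention). Everything is
#' reproducible from `seed`; the caller's RNG state is untouched.
#'
#' @param n,p,K,d,q cohort size, nodes, communities, latent rank,
#'   covariates.
#' @param gamma_sparsity fraction (in expectation) of unique `Gamma*`
#'   entries that are exactly zero.
#' @param effect_size absolute value of nonzero `Gamma*` entries.
#' @param noise_sd edge noise standard deviation.
#' @param theta_scale scale of the latent positions (see above).
#' @param seed integer seed.
#' @param trace_adjust if `TRUE`, subtract the block-constant matrix that
#'   makes `Tr(W' Theta* W) = 0` (the identifiability convention of the
#'   unpenalized model; off by default since the estimator does not impose
#'   it).
#' @return list with `A` ([adjacency_stack()]), `X` ([covariate_table()]),
#'   `partition` ([community_partition()]), and `truth` (class
#'   `"msnr_truth"`: `V`, `theta_true`, `gammas_true`, `noise_sd`, `X`,
#'   `partition`, `seed`).
#' @examples
#' sim <- simulate_msnr(n = 10, p = 12, K = 3, d = 2, q = 2, seed = 1)
#' sim$A
#' @export
simulate_msnr <- function(n = 200L, p = 60L, K = 6L, d = 3L, q = 3L,
                          gamma_sparsity = 0.7, effect_size = 0.5,
                          noise_sd = 0.5, theta_scale = 1, seed = NULL,
                          trace_adjust = FALSE) {
  stopifnot(n >= 2, p >= 2, K >= 1, K <= p, d >= 1, d < p, q >= 1,
            gamma_sparsity >= 0, gamma_sparsity <= 1, effect_size >= 0,
            noise_sd >= 0, theta_scale > 0)
  with_seed(seed, {
    sizes <- diff(floor(seq(0, p, length.out = K + 1L)))
    labels <- paste0("comm", seq_len(K))
    assignment <- stats::setNames(rep(labels, times = sizes),
                                  paste0("v", seq_len(p)))
    partition <- community_partition(assignment)
    W <- partition$membership

    X <- matrix(stats::rnorm(n * q), n, q)
    X <- scale(X)                         # exact mean 0, sd 1 per column
    attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
    colnames(X) <- paste0("x", seq_len(q))

    V <- matrix(stats::rnorm(p * d, sd = sqrt(theta_scale^2 / sqrt(d))), p, d)
    theta <- V %*% t(V)
    if (trace_adjust) {
      tr <- sum(diag(crossprod(W, theta %*% W)))
      theta <- theta - tr / sum(as.numeric(partition$sizes)^2)
    }

    ut <- upper.tri(matrix(0, K, K), diag = TRUE)
    gammas <- lapply(seq_len(q), function(f) {
      nz <- stats::runif(sum(ut)) < (1 - gamma_sparsity)
      vals <- ifelse(nz, effect_size * sample(c(-1, 1), sum(ut), replace = TRUE), 0)
      G <- matrix(0, K, K)
      G[ut] <- vals
      G <- G + t(G)
      diag(G) <- diag(G) / 2
      G
    })

    vals <- array(0, dim = c(n, p, p))
    sut <- upper.tri(matrix(0, p, p))
    for (i in seq_len(n)) {
      M <- theta
      for (f in seq_len(q)) {
        if (any(gammas[[f]] != 0)) M <- M + X[i, f] * (W %*% gammas[[f]] %*% t(W))
      }
      if (noise_sd > 0) {
        E <- matrix(0, p, p)
        E[sut] <- stats::rnorm(sum(sut), sd = noise_sd)
        M <- M + E + t(E)
      }
      vals[i, , ] <- zero_diag(M)
    }
    A <- adjacency_stack(vals)
    ct <- covariate_table(X, subject_ids = A$subject_ids)
    truth <- structure(
      list(V = V, theta_true = theta, gammas_true = gammas,
           noise_sd = noise_sd, X = X, partition = partition, seed = seed),
      class = "msnr_truth"
    )
    list(A = A, X = ct, partition = partition, truth = truth)
  })
}

#' @rdname simulate_msnr
#' @details `simulate_msnr_null()` is the null-world generator: identical
#'   in every respect except all `Gamma*` are exactly zero
#'   (`gamma_sparsity = 1`), so connectivity carries no covariate signal.
#'   Used for type-I error calibration of the permutation test.
#' @export
simulate_msnr_null <- function(n = 200L, p = 60L, K = 6L, d = 3L, q = 3L,
                               noise_sd = 0.5, theta_scale = 1, seed = NULL) {
  simulate_msnr(n = n, p = p, K = K, d = d, q = q, gamma_sparsity = 1,
                effect_size = 0, noise_sd = noise_sd,
                theta_scale = theta_scale, seed = seed)
}
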