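#' Ordinary least squares with per-coefficient t-tests
#'
#' Fits `y ~ 1 + X` by OLS and returns coefficients, standard errors and
#' two-sided t-test p-values. This is the unit of both single-scale
#' comparators (one regression per edge, or per community mean); covariates
#' enter unstandardized with an intercept, mirroring the formula interface
#' `edge ~ age + sex + motion`.
#'
#' @param y numeric response vector of length `n`.
#' @param X `n x q` covariate matrix (no intercept column; one is added).
#' @return list with `coefficients`, `se`, `p_values` (each of length
#'   `q + 1`, intercept first), `sigma2`, `df`.
#' @export
ols_fit <- function(y, X) {
  out <- ols_fit_multi(matrix(y, ncol = 1L), X)
  list(coefficients = out$coefficients[, 1L], se = out$se[, 1L],
       p_values = out$p_values[, 1L], sigma2 = out$sigma2[1L], df = out$df)
}

# Vectorized OLS over many response columns sharing one design. Y: n x m.
# Returns (q+1) x m matrices of coefficients, ses, p-values.
ols_fit_multi <- function(Y, X) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  D <- cbind(`(Intercept)` = 1, X)
  k <- ncol(D)
  if (n <= k) stopf("need n > q + 1 observations (n = %d, q = %d)", n, k - 1L)
  qrD <- qr(D)
  if (qrD$rank < k) stopf("rank-deficient design")
  coefs <- qr.coef(qrD, Y)
  res <- Y - D %*% coefs
  df <- n - k
  sigma2 <- colSums(res^2) / df
  xtx_inv_diag <- diag(chol2inv(qr.R(qrD)))
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  tval <- coefs / se
  pv <- 2 * stats::pt(-abs(tval), df)
  dimnames(coefs) <- dimnames(se) <- dimnames(pv) <-
    list(colnames(D), colnames(Y))
  list(coefficients = coefs, se = se, p_values = pv, sigma2 = sigma2, df = df)
}

#' Within- and between-community mean connectivity
#'
#' For each subject, the within-community connectivity of community `C_k`
#' is `sum_{j != j' in C_k} A_jj' / (|C_k| (|C_k| - 1))` and the
#' between-community connectivity of pair `(k, k')` is
#' `sum_{j in C_k, j' in C_k'} A_jj' / (|C_k| |C_k'|)`. Columns are the `K`
#' within means first, then the unordered between pairs in lexicographic
#' order. Within columns of singleton communities are undefined and are
#' dropped with a warning.
#'
#' @param A an [adjacency_stack()].
#' @param partition a [community_partition()].
#' @return `n x (K + K(K-1)/2)` matrix (minus dropped singleton columns),
#'   with attribute `"blocks"` (data frame of `k1`, `k2` per column).
#' @export
community_means <- function(A, partition) {
  bs <- block_summary(A, partition)
  within <- which(bs$k1 == bs$k2)
  between <- which(bs$k1 != bs$k2)
  drop_within <- within[bs$counts[within] == 0]
  if (length(drop_within) > 0L) {
    warnf("dropping within column(s) for singleton community(ies): %s",
          paste(partition$labels[bs$k1[drop_within]], collapse = ", "))
    within <- setdiff(within, drop_within)
  }
  ord <- c(within, between)
  out <- bs$means[, ord, drop = FALSE]
  labs <- partition$labels
  colnames(out) <- ifelse(bs$k1[ord] == bs$k2[ord],
                          paste0("within_", labs[bs$k1[ord]]),
                          paste0("between_", labs[bs$k1[ord]], "_", labs[bs$k2[ord]]))
  attr(out, "blocks") <- data.frame(k1 = bs$k1[ord], k2 = bs$k2[ord])
  out
}

#' False discovery rate correction
#'
#' Benjamini-Hochberg step-up control at level `q_level` (default), or
#' Storey q-values with the standard pi0 estimate at threshold 0.5
#' (`pi0 = min(1, mean(p > 0.5) / 0.5)`).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q_level target FDR level (default 0.05).
#' @param method `"BH"` or `"storey"`.
#' @return logical rejection mask of the same length.
#' @export
fdr_correct <- function(p_values, q_level = 0.05, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (length(p_values) == 0L) stopf("empty p-value vector")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stopf("p-values must be in [0, 1]")
  if (method == "BH") {
    return(stats::p.adjust(p_values, method = "BH") <= q_level)
  }
  m <- length(p_values)
  pi0 <- min(1, max(mean(p_values > 0.5) / 0.5, 1 / m))
  ord <- order(p_values, decreasing = TRUE)
  qv <- numeric(m)
  running <- 1
  for (i in seq_len(m)) {
    j <- ord[i]
    running <- min(running, pi0 * m * p_values[j] / (m - i + 1L))
    qv[j] <- running
  }
  qv <= q_level
}

# Upper-triangle (j < j') index helper for p x p symmetric matrices.
upper_tri_index <- function(p) which(upper.tri(matrix(0, p, p)))

# Fold a length-p(p-1)/2 vector of upper-triangle values into a symmetric
# p x p matrix with zero diagonal.
unfold_sym <- function(v, p) {
  M <- matrix(0, p, p)
  M[upper.tri(M)] <- v
  M + t(M)
}

#' Mass-univariate edge model
#'
#' The micro-scale comparator: one OLS regression per upper-triangle edge
#' on the raw covariates plus intercept, with FDR correction of the slope
#' p-values. Out-of-sample prediction uses all fitted edge models (not only
#' FDR-significant ones; this is optimistic by construction) and the same
#' shared error routine as the multi-scale model.
#'
#' @param A_train,A_test [adjacency_stack()]s.
#' @param X_train,X_test raw-scale [covariate_table()]s (or matrices).
#' @param q_level FDR level for the rejection masks.
#' @param fdr_method `"BH"` or `"storey"` (see [fdr_correct()]).
#' @return list of class `"msnr_edge_model"`: `coefficients` (list of
#'   `q + 1` symmetric `p x p` matrices, intercept first), `p_values` and
#'   `fdr_mask` (lists of `q` matrices; mask entries are 0/1 off the
#'   diagonal, diagonal untested), `prediction_error`, `n_significant`
#'   (unique upper-triangle rejections per covariate).
#' @export
edge_model <- function(A_train, X_train, A_test, X_test, q_level = 0.05,
                       fdr_method = "BH") {
  Xtr <- raw_covariates(X_train)
  Xte <- raw_covariates(X_test)
  p <- n_nodes(A_train)
  ut <- upper_tri_index(p)
  Ytr <- t(apply(A_train$values, 1L, function(M) M[ut]))
  fit <- ols_fit_multi(Ytr, Xtr)
  q <- ncol(Xtr)
  coef_mats <- lapply(seq_len(q + 1L), function(j) unfold_sym(fit$coefficients[j, ], p))
  names(coef_mats) <- rownames(fit$coefficients)
  pv_mats <- lapply(seq_len(q), function(f) unfold_sym(fit$p_values[f + 1L, ], p))
  masks <- lapply(seq_len(q), function(f) {
    unfold_sym(as.numeric(fdr_correct(fit$p_values[f + 1L, ], q_level, fdr_method)), p)
  })
  names(pv_mats) <- names(masks) <- colnames(Xtr)
  pred_cols <- cbind(1, Xte) %*% fit$coefficients        # n_test x n_edges
  preds <- array(0, dim = c(nrow(Xte), p, p))
  for (i in seq_len(nrow(Xte))) preds[i, , ] <- unfold_sym(pred_cols[i, ], p)
  err <- stack_prediction_error(A_test, preds)
  structure(list(coefficients = coef_mats, p_values = pv_mats, fdr_mask = masks,
                 prediction_error = err,
                 n_significant = vapply(masks, function(M) sum(M[upper.tri(M)] != 0), 0)),
            class = "msnr_edge_model")
}

#' Community-mean model
#'
#' The meso-scale comparator: one OLS regression per within/between
#' community mean (see [community_means()]) on the raw covariates plus
#' intercept, with FDR correction. Edge-level predictions broadcast each
#' predicted block mean to every edge in its block (the unique
#' structure-preserving choice), so the prediction error is computed at the
#' edge level with the same shared routine as the other methods.
#'
#' @inheritParams edge_model
#' @param partition a [community_partition()].
#' @return list of class `"msnr_community_model"`: `response`
#'   (training community-mean matrix), `coefficients` (list of `q + 1`
#'   symmetric `K x K` matrices), `p_values`, `fdr_mask` (lists of `q`
#'   matrices; untested cells, e.g. singleton within blocks, are `NA`),
#'   `prediction_error`, `n_significant`.
#' @export
community_model <- function(A_train, X_train, A_test, X_test, partition,
                            q_level = 0.05, fdr_method = "BH") {
  Xtr <- raw_covariates(X_train)
  Xte <- raw_covariates(X_test)
  Ytr <- community_means(A_train, partition)
  blocks <- attr(Ytr, "blocks")
  fit <- ols_fit_multi(Ytr, Xtr)
  q <- ncol(Xtr)
  K <- n_communities(partition)
  to_mat <- function(v, fill = NA_real_) {
    M <- matrix(fill, K, K)
    M[cbind(blocks$k1, blocks$k2)] <- v
    M[cbind(blocks$k2, blocks$k1)] <- v
    M
  }
  coef_mats <- lapply(seq_len(q + 1L), function(j) to_mat(fit$coefficients[j, ], fill = 0))
  names(coef_mats) <- rownames(fit$coefficients)
  pv_mats <- lapply(seq_len(q), function(f) to_mat(fit$p_values[f + 1L, ]))
  masks <- lapply(seq_len(q), function(f) {
    to_mat(as.numeric(fdr_correct(fit$p_values[f + 1L, ], q_level, fdr_method)))
  })
  names(pv_mats) <- names(masks) <- colnames(Xtr)

  # Broadcast predicted block means to every edge of the block.
  pred_cols <- cbind(1, Xte) %*% fit$coefficients        # n_test x n_blocks
  W <- partition$membership
  bp <- list(k1 = blocks$k1, k2 = blocks$k2)
  p <- n_nodes(A_test)
  preds <- array(0, dim = c(nrow(Xte), p, p))
  for (i in seq_len(nrow(Xte))) {
    preds[i, , ] <- zero_diag(expand_blocks(pred_cols[i, ], bp, W))
  }
  err <- stack_prediction_error(A_test, preds)
  structure(list(response = Ytr, coefficients = coef_mats, p_values = pv_mats,
                 fdr_mask = masks, prediction_error = err,
                 n_significant = vapply(masks, function(M) {
                   sum(M[upper.tri(M, diag = TRUE)] != 0, na.rm = TRUE)
                 }, 0)),
            class = "msnr_community_model")
}

# Extract the raw covariate matrix from a covariate_table or matrix.
raw_covariates <- function(X) {
  if (inherits(X, "covariate_table")) X$raw else as.matrix(X)
}
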