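# Independent oracles used across the test suite. These deliberately avoid
# the package's solver code paths: objectives are written out entry by
# entry, and the whole-problem solver is a generic proximal-gradient
# (FISTA) method rather than exact block coordinate descent.

# Direct entry-by-entry evaluation of the penalized objective with the
# package's edge convention (predicted diagonal zeroed; loss excludes
# diagonal terms entirely). Matches msnr_objective().
oracle_objective_eq4 <- function(theta, gammas, Avals, Xs, membership,
                                 lambda1, lambda2) {
  n <- dim(Avals)[1L]
  p <- dim(Avals)[2L]
  q <- length(gammas)
  comm <- apply(membership, 1L, which.max)
  loss <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      for (jp in seq_len(p)) {
        if (j == jp) next
        pred <- theta[j, jp]
        for (f in seq_len(q)) {
          pred <- pred + Xs[i, f] * gammas[[f]][comm[j], comm[jp]]
        }
        loss <- loss + (Avals[i, j, jp] - pred)^2
      }
    }
  }
  nuc <- sum(abs(eigen(theta, symmetric = TRUE, only.values = TRUE)$values))
  l1 <- sum(vapply(gammas, function(G) sum(abs(G)), 0))
  loss + lambda1 * nuc + lambda2 * l1
}

# The solver's internal convex objective: the above plus the implicit
# n * sum(diag(theta)^2) ridge (equivalently, full-Frobenius loss with the
# community term's diagonal zeroed).
oracle_objective_internal <- function(theta, gammas, Avals, Xs, membership,
                                      lambda1, lambda2) {
  n <- dim(Avals)[1L]
  oracle_objective_eq4(theta, gammas, Avals, Xs, membership, lambda1, lambda2) +
    n * sum(diag(theta)^2)
}

# Generic convex solver for the internal objective: FISTA with backtracking
# line search and monotone restart over (theta, gamma_1..gamma_q).
oracle_solve_fista <- function(Avals, Xs, membership, lambda1, lambda2,
                               max_iter = 20000L, tol = 1e-14) {
  n <- dim(Avals)[1L]
  p <- dim(Avals)[2L]
  q <- ncol(Xs)
  W <- membership

  smooth_val_grad <- function(theta, gammas) {
    gt <- matrix(0, p, p)
    gg <- lapply(seq_len(q), function(f) matrix(0, ncol(W), ncol(W)))
    val <- 0
    for (i in seq_len(n)) {
      S <- matrix(0, p, p)
      for (f in seq_len(q)) S <- S + Xs[i, f] * (W %*% gammas[[f]] %*% t(W))
      diag(S) <- 0
      E <- Avals[i, , ] - theta - S          # diag(E) = -diag(theta)
      val <- val + sum(E^2)
      gt <- gt - 2 * E
      Eo <- E; diag(Eo) <- 0
      for (f in seq_len(q)) gg[[f]] <- gg[[f]] - 2 * Xs[i, f] * crossprod(W, Eo %*% W)
    }
    list(val = val, gt = (gt + t(gt)) / 2,
         gg = lapply(gg, function(G) (G + t(G)) / 2))
  }
  prox <- function(theta, gammas, t) {
    eg <- eigen(theta, symmetric = TRUE)
    d <- sign(eg$values) * pmax(abs(eg$values) - t * lambda1, 0)
    th <- eg$vectors %*% (d * t(eg$vectors))
    list(theta = (th + t(th)) / 2,
         gammas = lapply(gammas, function(G) sign(G) * pmax(abs(G) - t * lambda2, 0)))
  }
  penalty <- function(theta, gammas) {
    lambda1 * sum(abs(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)) +
      lambda2 * sum(vapply(gammas, function(G) sum(abs(G)), 0))
  }

  theta <- matrix(0, p, p)
  gammas <- lapply(seq_len(q), function(f) matrix(0, ncol(W), ncol(W)))
  yt <- theta; yg <- gammas
  tk <- 1
  step <- 1 / (4 * n)                         # conservative initial step
  obj_prev <- smooth_val_grad(theta, gammas)$val + penalty(theta, gammas)
  for (it in seq_len(max_iter)) {
    sg <- smooth_val_grad(yt, yg)
    repeat {
      cand <- prox(yt - step * sg$gt,
                   lapply(seq_len(q), function(f) yg[[f]] - step * sg$gg[[f]]),
                   step)
      dtheta <- cand$theta - yt
      dg <- lapply(seq_len(q), function(f) cand$gammas[[f]] - yg[[f]])
      lin <- sg$val + sum(sg$gt * dtheta) +
        sum(vapply(seq_len(q), function(f) sum(sg$gg[[f]] * dg[[f]]), 0))
      quad <- (sum(dtheta^2) + sum(vapply(dg, frob2_helper, 0))) / (2 * step)
      fval <- smooth_val_grad(cand$theta, cand$gammas)$val
      if (fval <= lin + quad + 1e-12 * max(1, abs(fval))) break
      step <- step / 2
    }
    obj <- fval + penalty(cand$theta, cand$gammas)
    if (obj > obj_prev) {                     # monotone restart
      yt <- theta; yg <- gammas; tk <- 1
      next
    }
    tk_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    yt <- cand$theta + ((tk - 1) / tk_next) * (cand$theta - theta)
    yg <- lapply(seq_len(q), function(f) {
      cand$gammas[[f]] + ((tk - 1) / tk_next) * (cand$gammas[[f]] - gammas[[f]])
    })
    theta <- cand$theta; gammas <- cand$gammas; tk <- tk_next
    if (abs(obj_prev - obj) < tol * max(1, obj_prev) && it > 10L) break
    obj_prev <- obj
  }
  list(theta = theta, gammas = gammas,
       objective = smooth_val_grad(theta, gammas)$val + penalty(theta, gammas))
}

frob2_helper <- function(M) sum(M^2)

# Brute-force per-block residual means by explicit index loops.
oracle_block_means <- function(Avals, comm) {
  n <- dim(Avals)[1L]
  K <- max(comm)
  out <- NULL
  for (k1 in seq_len(K)) {
    for (k2 in k1:K) {
      col <- numeric(n)
      cnt <- 0L
      for (i in seq_len(n)) {
        s <- 0; cnt <- 0L
        for (j in which(comm == k1)) {
          for (jp in which(comm == k2)) {
            if (k1 == k2 && j == jp) next
            if (k1 == k2) { s <- s + Avals[i, j, jp]; cnt <- cnt + 1L }
            else { s <- s + Avals[i, j, jp]; cnt <- cnt + 1L }
          }
        }
        col[i] <- if (cnt > 0) s / cnt else 0
      }
      out <- cbind(out, col)
    }
  }
  out
}

# Brute-force Benjamini-Hochberg step-up from its definition.
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0L
  for (i in seq_len(m)) if (p[ord[i]] <= q * i / m) k <- i
  rej <- rep(FALSE, m)
  if (k > 0L) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# Weighted-lasso oracle via glmnet on the same tiny objective:
#   min_g  m * sum_i (y_i - x_i' g)^2 + lambda2 * ||g||_1
oracle_weighted_lasso <- function(y, X, m, lambda2) {
  testthat::skip_if_not_installed("glmnet")
  n <- length(y)
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                        lambda = lambda2 / (2 * n * m),
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14)
  as.numeric(fit$beta)
}
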