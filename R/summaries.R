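#' Sparsity of the community-effect matrices
#'
#' Per covariate, the fraction of the `K(K+1)/2` unique entries (upper
#' triangle plus diagonal) of `Gamma^f` that are exactly zero.
#'
#' @param gammas a list of symmetric `K x K` matrices, a single matrix, or
#'   a fitted [msnr_model()].
#' @return numeric vector of fractions in `[0, 1]`, one per covariate.
#' @export
sparsity_fraction <- function(gammas) {
  gammas <- as_gamma_list(gammas)
  vapply(gammas, function(G) {
    u <- G[upper.tri(G, diag = TRUE)]
    mean(u == 0)
  }, 0)
}

#' Sign counts of community effects
#'
#' Counts strictly positive and strictly negative coefficients among the
#' within-community entries (the diagonal of `Gamma`) and the
#' between-community entries (the strict upper triangle), summarizing
#' whether a covariate predominantly strengthens or weakens connectivity
#' within vs between communities.
#'
#' @param gamma a symmetric `K x K` matrix.
#' @return named integer vector
#'   `(within_pos, within_neg, between_pos, between_neg)`.
#' @export
count_signs <- function(gamma) {
  gamma <- as.matrix(gamma)
  d <- diag(gamma)
  u <- gamma[upper.tri(gamma)]
  c(within_pos = sum(d > 0), within_neg = sum(d < 0),
    between_pos = sum(u > 0), between_neg = sum(u < 0))
}

#' Node coordinates
#'
#' Simple validated container for 3D node coordinates (mm, MNI-like
#' space), used for distance-dependence summaries.
#'
#' @param coords `p x 3` numeric matrix.
#' @param node_ids `p` node labels.
#' @return object of class `"node_coordinates"`.
#' @export
node_coordinates <- function(coords, node_ids = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stopf("coords must have 3 columns (x, y, z)")
  if (!all(is.finite(coords))) stopf("coordinates must be finite")
  if (is.null(node_ids)) node_ids <- rownames(coords)
  if (is.null(node_ids)) node_ids <- paste0("v", seq_len(nrow(coords)))
  if (length(node_ids) != nrow(coords)) stopf("one id per node required")
  rownames(coords) <- node_ids
  colnames(coords) <- c("x", "y", "z")
  structure(list(coords = coords, node_ids = as.character(node_ids)),
            class = "node_coordinates")
}

#' Mean inter-community Euclidean distances
#'
#' Entry `(k, k')` is the mean Euclidean distance over all node pairs
#' `j in C_k`, `j' in C_k'`; for `k = k'`, over distinct pairs (singleton
#' communities get `NA` within-distance). `method = "centroid"` instead
#' returns distances between community centroids.
#'
#' @param coords a [node_coordinates()] (rows aligned with the partition's
#'   node order).
#' @param partition a [community_partition()].
#' @param method `"pairs"` (mean over cross-community node pairs, default)
#'   or `"centroid"`.
#' @return symmetric `K x K` matrix.
#' @export
community_distances <- function(coords, partition, method = c("pairs", "centroid")) {
  method <- match.arg(method)
  stopifnot(inherits(coords, "node_coordinates"),
            inherits(partition, "community_partition"))
  if (nrow(coords$coords) != nrow(partition$membership)) {
    stopf("coordinate rows (%d) != partition nodes (%d)",
          nrow(coords$coords), nrow(partition$membership))
  }
  K <- n_communities(partition)
  if (method == "centroid") {
    W <- partition$membership
    cent <- sweep(crossprod(W, coords$coords), 1L, as.numeric(partition$sizes), "/")
    return(as.matrix(stats::dist(cent)))
  }
  D <- as.matrix(stats::dist(coords$coords))
  bp <- block_pairs(partition)
  bm <- block_mean_vec(D, partition, bp)
  bm[bp$m == 0] <- NA_real_
  out <- matrix(0, K, K, dimnames = list(partition$labels, partition$labels))
  out[cbind(bp$k1, bp$k2)] <- bm
  out[cbind(bp$k2, bp$k1)] <- bm
  out
}

#' Correlation between community effects and inter-community distance
#'
#' Pearson correlation (with two-sided p-value) between the unique entries
#' of a community-effect matrix `Gamma` and the corresponding mean
#' inter-community distances. A negative correlation for an in-scanner
#' motion covariate reproduces the classic distance-dependent motion
#' artifact: nearby regions' connectivity is inflated by movement.
#'
#' @param gamma symmetric `K x K` matrix.
#' @param distances symmetric `K x K` matrix (see [community_distances()]).
#' @param use `"all"` unique entries including exact zeros (default) or
#'   `"nonzero"` to drop entries where `gamma` is exactly zero.
#' @return list with `estimate` (Pearson r) and `p_value`.
#' @export
gamma_distance_cor <- function(gamma, distances, use = c("all", "nonzero")) {
  use <- match.arg(use)
  gamma <- as.matrix(gamma)
  distances <- as.matrix(distances)
  stopifnot(identical(dim(gamma), dim(distances)))
  ut <- upper.tri(gamma, diag = TRUE)
  g <- gamma[ut]
  d <- distances[ut]
  keep <- is.finite(d)
  if (use == "nonzero") keep <- keep & g != 0
  g <- g[keep]; d <- d[keep]
  if (length(g) < 3L) stopf("fewer than 3 usable entries")
  if (stats::sd(g) == 0 || stats::sd(d) == 0) {
    stopf("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(g, d, method = "pearson", alternative = "two.sided")
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' Post-fit interpretability report
#'
#' Bundles the sparsity fractions, per-covariate sign counts, and (when
#' coordinates are supplied) the effect-vs-distance correlations for a
#' fitted model.
#'
#' @param model a fitted [msnr_model()].
#' @param coords optional [node_coordinates()].
#' @param covariate_names optional labels for the covariates.
#' @return list of class `"msnr_summary"`.
#' @export
msnr_summarize <- function(model, coords = NULL, covariate_names = NULL) {
  gammas <- model$gammas
  if (is.null(covariate_names)) covariate_names <- paste0("x", seq_along(gammas))
  names(gammas) <- covariate_names
  out <- list(
    sparsity = stats::setNames(sparsity_fraction(gammas), covariate_names),
    sign_counts = lapply(gammas, count_signs)
  )
  if (!is.null(coords)) {
    Dc <- community_distances(coords, model$partition)
    out$distance_correlation <- lapply(gammas, function(G) {
      tryCatch(gamma_distance_cor(G, Dc), error = function(e) NULL)
    })
  }
  structure(out, class = "msnr_summary")
}

as_gamma_list <- function(gammas) {
  if (inherits(gammas, "msnr_model")) return(gammas$gammas)
  if (is.matrix(gammas)) return(list(gammas))
  stopifnot(is.list(gammas))
  gammas
}
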