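#' Node-to-community partition
#'
#' Builds the community membership structure used by the model: a map from
#' each of `p` nodes to one of `K` communities, the `p x K` binary indicator
#' matrix `W` (`W[j, k] = 1` iff node `j` belongs to community `k`), and the
#' community sizes. Community column order follows the first appearance of
#' each label along `node_order` (deterministic).
#'
#' @param assignment named vector (or unnamed, aligned with `node_order`)
#'   mapping node ids to community labels.
#' @param node_order character vector of node ids giving the row order of
#'   `W`. Defaults to `names(assignment)`.
#' @return an object of class `"community_partition"` with elements
#'   `assignment` (named character vector in node order), `labels` (K
#'   community labels), `membership` (`p x K` binary matrix `W`), `sizes`
#'   (named integer vector).
#' @examples
#' cp <- community_partition(c(a = "1", b = "1", c = "2"))
#' cp$membership
#' @export
community_partition <- function(assignment, node_order = NULL) {
  if (is.null(node_order)) {
    node_order <- names(assignment)
    if (is.null(node_order)) {
      node_order <- paste0("v", seq_along(assignment))
      names(assignment) <- node_order
    }
  }
  node_order <- as.character(node_order)
  if (anyDuplicated(node_order)) stopf("duplicated node ids in `node_order`")
  if (is.null(names(assignment))) {
    if (length(assignment) != length(node_order)) {
      stopf("unnamed `assignment` must have one entry per node")
    }
    names(assignment) <- node_order
  }
  missing <- setdiff(node_order, names(assignment))
  if (length(missing) > 0L) {
    stopf("unassigned node(s): %s (exclude unassigned nodes upstream at load)",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  lab <- as.character(assignment[node_order])
  labels <- unique(lab)          # column order: first appearance
  K <- length(labels)
  p <- length(node_order)
  W <- matrix(0L, p, K, dimnames = list(node_order, labels))
  W[cbind(seq_len(p), match(lab, labels))] <- 1L
  sizes <- colSums(W)
  storage.mode(sizes) <- "integer"
  structure(
    list(assignment = stats::setNames(lab, node_order),
         labels = labels,
         membership = W,
         sizes = sizes),
    class = "community_partition"
  )
}

#' @rdname community_partition
#' @param partition a `community_partition`.
#' @export
n_communities <- function(partition) length(partition$labels)

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition: %d nodes, %d communities (sizes %s)>\n",
              nrow(x$membership), n_communities(x),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

# Unordered community-pair bookkeeping shared by the solver and baselines.
# Pairs ordered (1,1), (1,2), ..., (1,K), (2,2), ..., (K,K) [lexicographic,
# k <= k']. Counts m are off-diagonal entry counts of each block in the full
# p x p matrix, counted once per unordered node pair position:
#   m_kk  = |C_k| (|C_k| - 1)   (ordered off-diagonal within-block entries)
#   m_kk' = |C_k| |C_k'|        (one orientation of the between block)
block_pairs <- function(partition) {
  K <- n_communities(partition)
  sizes <- as.numeric(partition$sizes)
  k1 <- rep(seq_len(K), times = K - seq_len(K) + 1L)
  k2 <- unlist(lapply(seq_len(K), function(k) k:K))
  m <- ifelse(k1 == k2, sizes[k1] * (sizes[k1] - 1), sizes[k1] * sizes[k2])
  list(k1 = k1, k2 = k2, m = m, n_blocks = length(m))
}
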