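#' Stack of subject-level connectivity matrices
#'
#' Container for `n` symmetric `p x p` weighted adjacency matrices (e.g.
#' Fisher-z transformed correlations), the response of multi-scale network
#' regression. Each slice is validated to be symmetric (within
#' `symmetrize_tol`, then symmetrized exactly by averaging with its
#' transpose), finite, and is given a zero diagonal; self-connectivity is
#' undefined for correlation-based networks and the diagonal carries no
#' information under the model's edge convention.
#'
#' @param values numeric array of dimension `n x p x p`, or a list of `n`
#'   `p x p` matrices.
#' @param subject_ids character vector of `n` subject labels (defaults to
#'   `"s1" ... "sn"`).
#' @param node_ids character vector of `p` node labels (defaults to
#'   `"v1" ... "vp"`).
#' @param symmetrize_tol maximum tolerated elementwise asymmetry
#'   `|A - t(A)|`; larger asymmetry is an error.
#' @return an object of class `"adjacency_stack"` with elements `values`
#'   (`n x p x p` array), `subject_ids`, `node_ids`.
#' @examples
#' A <- adjacency_stack(array(0, dim = c(2, 3, 3)))
#' n_subjects(A)
#' @export
adjacency_stack <- function(values, subject_ids = NULL, node_ids = NULL,
                            symmetrize_tol = 1e-8) {
  if (is.list(values)) {
    p <- nrow(values[[1L]])
    arr <- array(0, dim = c(length(values), p, p))
    for (i in seq_along(values)) arr[i, , ] <- values[[i]]
    values <- arr
  }
  if (!is.array(values) || length(dim(values)) != 3L || dim(values)[2L] != dim(values)[3L]) {
    stopf("`values` must be an n x p x p array or list of square matrices")
  }
  if (!all(is.finite(values))) stopf("adjacency values must all be finite")
  n <- dim(values)[1L]
  p <- dim(values)[2L]
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(n))
  if (is.null(node_ids)) node_ids <- paste0("v", seq_len(p))
  if (length(subject_ids) != n) stopf("need %d subject ids, got %d", n, length(subject_ids))
  if (length(node_ids) != p) stopf("need %d node ids, got %d", p, length(node_ids))
  if (anyDuplicated(subject_ids)) stopf("duplicated subject ids")

  warned_diag <- FALSE
  for (i in seq_len(n)) {
    Ai <- values[i, , ]
    asym <- max(abs(Ai - t(Ai)))
    if (asym > symmetrize_tol) {
      stopf("subject '%s': asymmetry %.3g exceeds tolerance %.3g",
            subject_ids[i], asym, symmetrize_tol)
    }
    Ai <- (Ai + t(Ai)) / 2
    if (!warned_diag && any(abs(diag(Ai)) > 0)) {
      warnf("nonzero diagonal entries found; zeroing (self-connectivity is excluded)")
      warned_diag <- TRUE
    }
    diag(Ai) <- 0
    values[i, , ] <- Ai
  }
  structure(
    list(values = values,
         subject_ids = as.character(subject_ids),
         node_ids = as.character(node_ids)),
    class = "adjacency_stack"
  )
}

#' @rdname adjacency_stack
#' @param A an `adjacency_stack`.
#' @export
n_subjects <- function(A) dim(A$values)[1L]

#' @rdname adjacency_stack
#' @export
n_nodes <- function(A) dim(A$values)[2L]

#' Subset an adjacency stack by subject
#'
#' @param x an `adjacency_stack`.
#' @param i subject indices (integer or logical).
#' @param ... unused.
#' @return an `adjacency_stack` with the selected subjects.
#' @export
`[.adjacency_stack` <- function(x, i, ...) {
  idx <- seq_len(n_subjects(x))[i]
  structure(
    list(values = x$values[idx, , , drop = FALSE],
         subject_ids = x$subject_ids[idx],
         node_ids = x$node_ids),
    class = "adjacency_stack"
  )
}

#' @export
print.adjacency_stack <- function(x, ...) {
  cat(sprintf("<adjacency_stack: %d subjects, %d nodes>\n",
              n_subjects(x), n_nodes(x)))
  invisible(x)
}
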