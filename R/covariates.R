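#' Subject covariate table
#'
#' Holds the `n x q` covariate matrix `X` together with its standardization
#' state. The model is always fit on column-standardized covariates
#' (mean 0, sd 1); test or validation subjects must be standardized with the
#' *training* statistics, never their own, so the centering/scaling vectors
#' travel with the object.
#'
#' @param X numeric `n x q` matrix (raw scale).
#' @param subject_ids `n` subject labels.
#' @param covariate_names `q` column labels (defaults to `colnames(X)`).
#' @return object of class `"covariate_table"` with elements `raw`,
#'   `centered_scaled` (`NULL` until standardized), `center`, `scale`,
#'   `subject_ids`, `covariate_names`.
#' @export
covariate_table <- function(X, subject_ids = NULL, covariate_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stopf("covariates must be finite")
  n <- nrow(X); q <- ncol(X)
  if (is.null(subject_ids)) subject_ids <- rownames(X)
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(n))
  if (length(subject_ids) != n) stopf("need %d subject ids", n)
  if (is.null(covariate_names)) covariate_names <- colnames(X)
  if (is.null(covariate_names)) covariate_names <- paste0("x", seq_len(q))
  dimnames(X) <- list(subject_ids, covariate_names)
  structure(
    list(raw = X, centered_scaled = NULL, center = NULL, scale = NULL,
         subject_ids = as.character(subject_ids),
         covariate_names = as.character(covariate_names)),
    class = "covariate_table"
  )
}

#' Standardize covariates
#'
#' `standardize_covariates()` centers and scales each column using the
#' table's own statistics (training use). `apply_standardization()` reuses
#' previously computed statistics (test/validation use), preventing
#' information leakage across the split.
#'
#' @param ct a `covariate_table`.
#' @return the table with `centered_scaled`, `center` and `scale` filled in.
#' @export
standardize_covariates <- function(ct) {
  stopifnot(inherits(ct, "covariate_table"))
  ctr <- colMeans(ct$raw)
  scl <- apply(ct$raw, 2L, stats::sd)
  if (any(scl <= 0 | !is.finite(scl))) {
    stopf("constant covariate column(s): %s",
          paste(ct$covariate_names[scl <= 0 | !is.finite(scl)], collapse = ", "))
  }
  apply_standardization(ct, ctr, scl)
}

#' @rdname standardize_covariates
#' @param center,scale numeric vectors of length `q` (training statistics).
#' @export
apply_standardization <- function(ct, center, scale) {
  stopifnot(inherits(ct, "covariate_table"))
  if (any(scale <= 0)) stopf("scale entries must be strictly positive")
  ct$centered_scaled <- sweep(sweep(ct$raw, 2L, center, "-"), 2L, scale, "/")
  ct$center <- center
  ct$scale <- scale
  ct
}

#' @rdname standardize_covariates
#' @export
is_standardized <- function(ct) !is.null(ct$centered_scaled)

#' Subset a covariate table by subject
#'
#' Subsetting drops any standardization state: statistics must be recomputed
#' on (or copied from) the relevant training set.
#'
#' @param x a `covariate_table`.
#' @param i subject indices.
#' @param ... unused.
#' @export
`[.covariate_table` <- function(x, i, ...) {
  covariate_table(x$raw[i, , drop = FALSE],
                  subject_ids = x$subject_ids[i],
                  covariate_names = x$covariate_names)
}

#' @export
print.covariate_table <- function(x, ...) {
  cat(sprintf("<covariate_table: %d subjects x %d covariates (%s)%s>\n",
              nrow(x$raw), ncol(x$raw),
              paste(x$covariate_names, collapse = ", "),
              if (is_standardized(x)) ", standardized" else ""))
  invisible(x)
}
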