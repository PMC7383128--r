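#' Read and write adjacency stacks as delimited text
#'
#' The on-disk interchange format is a directory of per-subject square
#' tab-delimited matrices named `<subject_id>.tsv` (no header, no row
#' names). Loading validates symmetry (asymmetry beyond `1e-8` is an
#' error; smaller asymmetry is symmetrized by averaging) and zeroes any
#' nonzero diagonal with a warning. Subjects are ordered by file name;
#' use [align_inputs()] to reorder by covariate-table ID join.
#'
#' @param path directory of `<subject_id>.tsv` files.
#' @param node_ids optional node labels (defaults to `v1..vp`).
#' @return an [adjacency_stack()].
#' @export
read_adjacency <- function(path, node_ids = NULL) {
  if (!dir.exists(path)) stopf("adjacency directory '%s' does not exist", path)
  files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) stopf("no .tsv matrices found under '%s'", path)
  mats <- lapply(files, function(f) {
    M <- as.matrix(utils::read.table(f, sep = "\t", header = FALSE))
    dimnames(M) <- NULL
    if (nrow(M) != ncol(M)) stopf("'%s' is not square", f)
    M
  })
  dims <- vapply(mats, nrow, 0L)
  if (length(unique(dims)) != 1L) stopf("matrix sizes differ across subjects")
  adjacency_stack(mats,
                  subject_ids = sub("\\.tsv$", "", basename(files)),
                  node_ids = node_ids)
}

#' @rdname read_adjacency
#' @param A an [adjacency_stack()].
#' @export
write_adjacency <- function(A, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_subjects(A))) {
    utils::write.table(fmt17(A$values[i, , ]),
                       file.path(path, paste0(A$subject_ids[i], ".tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a covariate table
#'
#' Delimited text with a header; first column `subject_id`, remaining
#' columns numeric covariates.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return a [covariate_table()].
#' @export
read_covariates <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = NA)
  if (ncol(df) < 2L) stopf("covariate file needs subject_id plus >= 1 covariate")
  X <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(X) <- "double"
  covariate_table(X, subject_ids = as.character(df[[1L]]),
                  covariate_names = colnames(df)[-1L])
}

#' @rdname read_covariates
#' @param ct a [covariate_table()].
#' @export
write_covariates <- function(ct, path, sep = "\t") {
  df <- data.frame(subject_id = ct$subject_ids, fmt17(ct$raw),
                   check.names = FALSE)
  colnames(df) <- c("subject_id", ct$covariate_names)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a node-to-community partition table
#'
#' Delimited text with header columns `node_id` and `community_label`.
#' Returns the raw map; the partition object is built against the
#' adjacency's node order by [align_inputs()] or [community_partition()].
#'
#' @param path file path.
#' @param sep field separator.
#' @return named character vector (names = node ids).
#' @export
read_partition <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character")
  if (ncol(df) < 2L) stopf("partition file needs node_id and community_label")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Read node coordinates
#'
#' Delimited text with header columns `node_id`, `x`, `y`, `z`.
#'
#' @param path file path.
#' @param sep field separator.
#' @return a [node_coordinates()].
#' @export
read_coordinates <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(df) < 4L) stopf("coordinate file needs node_id, x, y, z")
  node_coordinates(as.matrix(df[, 2:4]), node_ids = as.character(df[[1L]]))
}

#' Align adjacency, covariates, partition and coordinates
#'
#' Subjects are matched by ID join between the adjacency stack and the
#' covariate table (unmatched subjects on either side are an error, never
#' a silent drop); the covariate rows are reordered to the adjacency's
#' subject order. Node order is taken from the adjacency container; the
#' partition map and coordinates are reindexed to it (a node missing from
#' the partition map is an "unassigned node" error).
#'
#' @param A an [adjacency_stack()].
#' @param X a [covariate_table()].
#' @param partition_map named vector from [read_partition()], or a
#'   [community_partition()] already in node order.
#' @param coords optional [node_coordinates()].
#' @return list with `A`, `X`, `partition`, and optionally `coords`.
#' @export
align_inputs <- function(A, X, partition_map, coords = NULL) {
  stopifnot(inherits(A, "adjacency_stack"), inherits(X, "covariate_table"))
  extra_a <- setdiff(A$subject_ids, X$subject_ids)
  extra_x <- setdiff(X$subject_ids, A$subject_ids)
  if (length(extra_a) || length(extra_x)) {
    stopf("subject ID mismatch: %d adjacency-only, %d covariate-only (e.g. %s)",
          length(extra_a), length(extra_x),
          paste(utils::head(c(extra_a, extra_x), 3L), collapse = ", "))
  }
  X <- X[match(A$subject_ids, X$subject_ids)]
  partition <- if (inherits(partition_map, "community_partition")) {
    if (!identical(names(partition_map$assignment), A$node_ids)) {
      community_partition(partition_map$assignment, node_order = A$node_ids)
    } else partition_map
  } else {
    community_partition(partition_map, node_order = A$node_ids)
  }
  out <- list(A = A, X = X, partition = partition)
  if (!is.null(coords)) {
    idx <- match(A$node_ids, coords$node_ids)
    if (anyNA(idx)) stopf("coordinates missing for some nodes")
    out$coords <- node_coordinates(coords$coords[idx, , drop = FALSE],
                                   node_ids = A$node_ids)
  }
  out
}

#' Serialize model-selection results
#'
#' Writes the grids and error matrix (or the null error distribution) as
#' delimited text plus a JSON provenance summary (chosen penalties,
#' p-value, z-score, seeds). All numerics use 17 significant digits so a
#' read-back round-trips bit-identically.
#'
#' @param cv an [cross_validate()] result.
#' @param dir output directory (created if needed).
#' @export
write_cv_result <- function(cv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  em <- fmt17(cv$error_matrix)
  dimnames(em) <- list(fmt17(cv$grid1), fmt17(cv$grid2))
  utils::write.table(em, file.path(dir, "cv_error_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(data.frame(fold = cv$fold_assignment),
                     file.path(dir, "cv_folds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_summary(list(
    best_lambda1 = cv$best[["lambda1"]], best_lambda2 = cv$best[["lambda2"]],
    min_cv_error = min(cv$error_matrix),
    refinement_round = cv$refinement_round, seed = cv$seed
  ), file.path(dir, "cv_summary.json"))
  invisible(dir)
}

#' @rdname write_cv_result
#' @param perm an [permutation_test()] result.
#' @export
write_permutation_result <- function(perm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(null_error = fmt17(perm$null_errors)),
                     file.path(dir, "null_errors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_summary(list(
    observed_error = perm$observed_error, p_value = perm$p_value,
    z_score = perm$z_score, n_perm = perm$n_perm, seed = perm$seed,
    best_lambda1 = perm$observed_best[["lambda1"]],
    best_lambda2 = perm$observed_best[["lambda2"]]
  ), file.path(dir, "permutation_summary.json"))
  invisible(dir)
}

#' @rdname write_cv_result
#' @param model a fitted [msnr_model()].
#' @export
write_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(fmt17(model$theta), file.path(dir, "theta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (f in seq_along(model$gammas)) {
    utils::write.table(fmt17(model$gammas[[f]]),
                       file.path(dir, sprintf("gamma_%d.tsv", f)),
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  summ <- list(lambda1 = model$lambda1, lambda2 = model$lambda2,
               q = length(model$gammas),
               center = model$center, scale = model$scale)
  if (!is.null(model$diagnostics)) {
    summ$converged <- model$diagnostics$converged
    summ$n_iterations <- model$diagnostics$n_iterations
    summ$objective_trajectory <- model$diagnostics$objective_trajectory
    summ$trace_WtThetaW <- model$diagnostics$trace_WtThetaW
  }
  write_json_summary(summ, file.path(dir, "model_summary.json"))
  invisible(dir)
}

#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment; values that
#' parse as numbers become numeric.
#'
#' @param path file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stopf("malformed config line: '%s'", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

# 17 significant digits: round-trip-safe text serialization of doubles.
fmt17 <- function(x) {
  out <- format(x, digits = 17, trim = TRUE, scientific = NA)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

write_json_summary <- function(x, path) {
  x$package_version <- as.character(utils::packageVersion("msnr"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
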