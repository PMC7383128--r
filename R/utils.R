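# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps user-level seeding side-effect free.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Scalar / vector soft-thresholding operator S(z, t) = sign(z) * max(|z| - t, 0).
soft_threshold <- function(z, t) {
  sign(z) * pmax(abs(z) - t, 0)
}

# Zero the diagonal of a square matrix.
zero_diag <- function(M) {
  diag(M) <- 0
  M
}

# Squared Frobenius norm.
frob2 <- function(M) sum(M^2)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
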