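# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages derive their own RNG stream from the single
#' cohort/run seed so that regenerating any one component is reproducible
#' without replaying the others. Kept below 2^31 - 1 so the result is a
#' valid R integer seed.
#'
#' @param seed master integer seed.
#' @param stream character stream name.
#' @return an integer seed.
#' @keywords internal
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Repair a non-positive-definite correlation matrix
#'
#' Floors the eigenvalues of a symmetric matrix at `floor_at`, reconstructs,
#' and rescales to unit diagonal. Used when a group perturbation pushes a
#' target correlation matrix outside the positive-definite cone.
#'
#' @param R symmetric matrix.
#' @param floor_at eigenvalue floor used when a repair is needed.
#' @param warn emit a warning when a repair was actually needed.
#' @return a positive-semidefinite correlation matrix (repaired only when
#'   genuinely indefinite; near-zero eigenvalues from a semidefinite
#'   construction are left untouched).
#' @keywords internal
ensure_pd <- function(R, floor_at = 1e-8, warn = TRUE) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= -1e-12) return(R)
  if (warn) {
    warning(sprintf(
      "target covariance not positive definite (min eigenvalue %.3g); repaired by eigenvalue flooring",
      min(e$values)))
  }
  v <- pmax(e$values, floor_at)
  R2 <- e$vectors %*% (v * t(e$vectors))
  R2 <- stats::cov2cor((R2 + t(R2)) / 2)
  dimnames(R2) <- dimnames(R)
  R2
}

# Zero the diagonal and force exact symmetry (average of M and t(M)).
symmetrize0 <- function(M) {
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}

# Default region labels R001..R<N>.
default_regions <- function(n) sprintf("R%03d", seq_len(n))
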