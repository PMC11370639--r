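#' Propagate expression over the PPI network
#'
#' Computes the interactive effect `F`, the minimizer of the
#' Laplacian-regularized smoothing objective
#' `||F - X||_F^2 + mu * tr(F' L F)`, in closed form as the solution of
#' `(I + mu L) F = X`. The system matrix is symmetric positive definite
#' for mu >= 0, so a single Cholesky factorization is reused for all
#' sample columns; no explicit inverse is formed.
#'
#' @param X Numeric matrix, proteins x samples (independent effect).
#' @param L Graph Laplacian from [graph_laplacian()], same protein order
#'   as the rows of `X`.
#' @param mu Smoothness, a scalar >= 0. `mu = 0` returns `X` unchanged;
#'   large `mu` pulls each connected component towards its column mean.
#' @return Matrix `F` of the same shape and dimnames as `X`.
#' @seealso [combine_effects()] for mixing `F` back with `X`.
#' @export
propagate <- function(X, L, mu) {
  X <- as.matrix(X)
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu)) {
    stop("mu must be a single numeric value")
  }
  if (mu < 0) stop("mu must be >= 0, got ", mu)
  if (nrow(X) != nrow(L) || nrow(L) != ncol(L)) {
    stop("dimension mismatch: X is ", nrow(X), " x ", ncol(X),
         ", L is ", nrow(L), " x ", ncol(L))
  }
  if (mu == 0) return(X)
  Fmat <- phi_solve(L, mu, X)
  dimnames(Fmat) <- dimnames(X)
  Fmat
}

# Cholesky factor of Phi = I + mu * L; the factor is the reusable object
# passed to phi_solve_chol during training so each epoch factorizes once.
phi_chol <- function(L, mu) {
  Phi <- diag(nrow(L)) + mu * L
  R <- tryCatch(chol(Phi),
                error = function(e) {
                  stop("factorization of I + mu*L failed (mu = ", mu,
                       ", reciprocal condition estimate ",
                       format(rcond(Phi), digits = 3), "): ",
                       conditionMessage(e))
                })
  R
}

phi_solve_chol <- function(R, B) {
  backsolve(R, forwardsolve(R, B, upper.tri = TRUE, transpose = TRUE))
}

phi_solve <- function(L, mu, B) {
  phi_solve_chol(phi_chol(L, mu), B)
}

#' Combine independent and interactive effects
#'
#' The combining logit `alpha` is mapped to `theta = 1/(1 + exp(-alpha))`
#' so the weight on the interactive effect stays in (0, 1) during
#' training, and the combined effect is the convex combination
#' `Z = theta * F + (1 - theta) * X`.
#'
#' @param X Independent effect, proteins x samples.
#' @param F Interactive effect from [propagate()], same shape as `X`.
#' @param alpha Combining logit (scalar).
#' @return List with `theta` (scalar) and `Z` (matrix).
#' @export
combine_effects <- function(X, F, alpha) {
  X <- as.matrix(X); F <- as.matrix(F)
  if (!all(dim(X) == dim(F))) {
    stop("shape mismatch: X is ", nrow(X), " x ", ncol(X),
         ", F is ", nrow(F), " x ", ncol(F))
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha)) {
    stop("alpha must be a single numeric value")
  }
  theta <- stats::plogis(alpha)
  Z <- theta * F + (1 - theta) * X
  list(theta = theta, Z = Z)
}

#' Export an effect matrix as TSV
#'
#' Writes a proteins x samples matrix (e.g. the combined effect `Z`) in
#' the same layout the expression reader consumes: first column protein
#' symbols, header row of sample ids. Useful for feeding the combined
#' effect to external classifiers.
#'
#' @param Z Numeric matrix with protein rownames and sample colnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_combined_effect <- function(Z, path) {
  Z <- as.matrix(Z)
  if (is.null(rownames(Z)) || is.null(colnames(Z))) {
    stop("Z must carry protein rownames and sample colnames")
  }
  write_expression(Z, path)
}
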