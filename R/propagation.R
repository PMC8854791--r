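#' Normalize a similarity matrix for label propagation
#'
#' The default `"sum"` mode divides each entry by the sum of its row and
#' column totals, `N(i, j) = S(i, j) / (rowsum_i(S) + colsum_j(S))`; for a
#' symmetric S this is `S(i, j) / (deg(i) + deg(j))`, a Laplacian-style
#' normalization whose spectral radius is at most 1/2 (entrywise
#' `N <= D^-1/2 S D^-1/2 / 2`). The `"symmetric"` mode is the familiar
#' `D^-1/2 S D^-1/2`, provided for sensitivity checks. Entries whose
#' denominator is zero are set to 0 by convention, so all-zero rows never
#' produce NaN.
#'
#' @param S a symmetric nonnegative [SimilarityMatrix-class].
#' @param method `"sum"` (default) or `"symmetric"`.
#' @return a [SimilarityMatrix-class] of kind `"normalized"`.
#' @examples
#' S <- SimilarityMatrix(matrix(c(0, 1, 1, 0), 2, 2,
#'   dimnames = list(c("a", "b"), c("a", "b"))), kind = "integrated")
#' normalizeSimilarity(S)  # off-diagonal entries 1/(1+1) = 0.5
#' @export
normalizeSimilarity <- function(S, method = c("sum", "symmetric")) {
  method <- match.arg(method)
  stopifnot(is(S, "SimilarityMatrix"))
  m <- S@.Data
  if (method == "sum") {
    den <- outer(rowSums(m), colSums(m), "+")
  } else {
    d <- rowSums(m)
    den <- sqrt(outer(d, d))
  }
  N <- ifelse(den > 0, m / den, 0)
  dimnames(N) <- dimnames(m)
  SimilarityMatrix(N, kind = "normalized")
}

#' Label propagation to a fixed point
#'
#' Iterates `F(t+1) = retention * N %*% F(t) + (1 - retention) * Y` from
#' `F(0) = Y` until the maximum absolute elementwise change drops below
#' `tol`. Before iterating, the spectral radius of `retention * N` is
#' checked to be below 1 (which guarantees convergence to the unique fixed
#' point `(1 - retention) * solve(I - retention * N) %*% Y`); the call
#' fails fast otherwise. The number of iterations performed is attached as
#' attribute `"iterations"`.
#'
#' @param N a normalized [SimilarityMatrix-class] (see
#'   [normalizeSimilarity()]).
#' @param Y numeric initial label matrix with as many rows as `N`; for the
#'   lncRNA side this is `LD`, for the disease side `t(LD)`.
#' @param retention neighbour-retention rate in \[0, 1\].
#' @param tol convergence threshold on the max-abs update; default 1e-6.
#' @param maxIter iteration cap; default 1000.
#' @return the converged score matrix (plain numeric matrix with `Y`'s
#'   dimnames and attribute `"iterations"`).
#' @export
propagateLabels <- function(N, Y, retention, tol = 1e-6, maxIter = 1000L) {
  stopifnot(is(N, "SimilarityMatrix"))
  Nm <- N@.Data
  Y <- as.matrix(Y)
  if (nrow(Nm) != nrow(Y))
    lparpError("dimension", "N and Y row counts differ")
  if (retention < 0 || retention > 1)
    lparpError("domain", "retention must be in [0, 1]")
  if (retention > 0) {
    ev <- eigen(Nm, symmetric = isSymmetric(Nm), only.values = TRUE)$values
    rho <- max(Mod(ev)) * retention
    if (rho >= 1)
      lparpError("convergence",
        sprintf("spectral radius of retention * N is %.4f >= 1; propagation would not converge",
                rho))
  }
  Fmat <- Y
  inject <- (1 - retention) * Y
  for (it in seq_len(maxIter)) {
    Fnew <- retention * (Nm %*% Fmat) + inject
    res <- max(abs(Fnew - Fmat))
    Fmat <- Fnew
    if (res < tol) {
      attr(Fmat, "iterations") <- it
      return(Fmat)
    }
  }
  lparpError("convergence",
    sprintf("no convergence after %d iterations (residual %.3g >= tol %.3g)",
            maxIter, res, tol))
}

#' Average the two propagation fixed points into the estimated score
#'
#' `Fe = (FL + t(FD)) / 2`, where `FL` is the lncRNA-side fixed point
#' (`n_l x n_d`) and `FD` the disease-side fixed point (`n_d x n_l`).
#'
#' @param FL lncRNA-side propagated matrix, `n_l x n_d`.
#' @param FD disease-side propagated matrix, `n_d x n_l`.
#' @return a [ScoreMatrix-class], `n_l x n_d`.
#' @export
estimatedScore <- function(FL, FD) {
  FL <- as.matrix(FL); FD <- as.matrix(FD)
  if (!identical(dim(FL), rev(dim(FD))))
    lparpError("dimension", "FD must be the transpose shape of FL")
  ScoreMatrix((FL + t(FD)) / 2)
}
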