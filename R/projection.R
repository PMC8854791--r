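## Stage-two refinement: project the integrated similarities onto the
## column-normalized estimated scores. Despite the historical name
## "random projection" for this step, Eqs here are fully deterministic:
## no randomness is introduced and no seed is consumed.

#' Project lncRNA similarities onto estimated score columns
#'
#' `LDpl(i, j) = LLf(i, ) . Fe(, j) / ||Fe(, j)||_2`, i.e. the integrated
#' lncRNA similarity matrix times the column-normalized estimated score
#' matrix. Columns of `Fe` with zero norm yield a zero output column
#' (0/0 -> 0 convention; keeps isolated-disease predictions defined).
#'
#' @param LLf integrated lncRNA [SimilarityMatrix-class], `n_l x n_l`.
#' @param Fe estimated [ScoreMatrix-class], `n_l x n_d`.
#' @return a [ScoreMatrix-class], `n_l x n_d`.
#' @export
projectLncRNA <- function(LLf, Fe) {
  stopifnot(is(LLf, "SimilarityMatrix"))
  Fm <- as.matrix(Fe)
  if (ncol(LLf) != nrow(Fm))
    lparpError("dimension", "LLf column count must equal Fe row count")
  nrm <- sqrt(colSums(Fm^2))
  scale <- ifelse(nrm > 0, 1 / nrm, 0)
  ScoreMatrix(LLf@.Data %*% sweep(Fm, 2L, scale, "*"))
}

#' Project disease similarities onto estimated score rows
#'
#' Disease-side analogue of [projectLncRNA()], applied to the transposed
#' estimated scores: the result is `n_d x n_l` with entry
#' `(d, l) = DDf(d, ) . Fe(l, ) / ||Fe(l, )||_2`. Zero-norm rows of `Fe`
#' yield zero output entries.
#'
#' @param DDf integrated disease [SimilarityMatrix-class], `n_d x n_d`.
#' @param Fe estimated [ScoreMatrix-class], `n_l x n_d`.
#' @return a [ScoreMatrix-class], `n_d x n_l` (disease side).
#' @export
projectDisease <- function(DDf, Fe) {
  stopifnot(is(DDf, "SimilarityMatrix"))
  Fm <- as.matrix(Fe)
  if (ncol(DDf) != ncol(Fm))
    lparpError("dimension", "DDf column count must equal Fe column count")
  Ft <- t(Fm)
  nrm <- sqrt(colSums(Ft^2))  # row norms of Fe
  scale <- ifelse(nrm > 0, 1 / nrm, 0)
  ScoreMatrix(DDf@.Data %*% sweep(Ft, 2L, scale, "*"))
}

#' Combine the two projections into the final prediction
#'
#' `LD* = (LDpl + t(LDpd)) / 2`.
#'
#' @param LDpl lncRNA-side projection, `n_l x n_d`.
#' @param LDpd disease-side projection, `n_d x n_l`.
#' @return a [ScoreMatrix-class], `n_l x n_d`.
#' @export
finalScore <- function(LDpl, LDpd) {
  Lm <- as.matrix(LDpl); Dm <- as.matrix(LDpd)
  if (!identical(dim(Lm), rev(dim(Dm))))
    lparpError("dimension", "LDpd must be the transpose shape of LDpl")
  ScoreMatrix((Lm + t(Dm)) / 2)
}

#' Full two-stage prediction pipeline
#'
#' Runs the whole method on a known association matrix and optional
#' similarity inputs: (1) GIP kernels are computed on both axes and
#' integrated with the supplied disease semantic similarity `DD` and
#' lncRNA functional similarity `LL` (GIP-only where these are `NULL` or
#' zero); (2) both integrated networks are normalized and the known
#' labels propagated to their fixed points, averaged into the estimated
#' score `Fe`; (3) the integrated similarities are projected onto the
#' normalized `Fe` and averaged into the final score `LD*`. Higher scores
#' rank candidate pairs as more likely associations.
#'
#' @param LD an [AssociationMatrix-class] with at least one association.
#' @param DD optional disease [SimilarityMatrix-class] (semantic), indexed
#'   like `LD`'s diseases.
#' @param LL optional lncRNA [SimilarityMatrix-class] (functional),
#'   indexed like `LD`'s lncRNAs.
#' @param propagation a [PropagationParams-class].
#' @param gip a [GipParams-class].
#' @return a [ScoreMatrix-class] `LD*` (`n_l x n_d`), with attribute
#'   `"iterations"` = c(lncRNA = ..., disease = ...) recording the
#'   propagation iteration counts.
#' @examples
#' sim <- separableInstance(6, 6)
#' sc <- lparpPredict(sim$LD, sim$DD, sim$LL)
#' sc
#' @export
lparpPredict <- function(LD, DD = NULL, LL = NULL,
                         propagation = PropagationParams(),
                         gip = GipParams()) {
  stopifnot(is(LD, "AssociationMatrix"), is(propagation, "PropagationParams"),
            is(gip, "GipParams"))
  if (sum(LD@.Data) < 1)
    lparpError("empty_input", "LD must contain at least one known association")
  if (!is.null(LL) && !identical(rownames(LL), rownames(LD)))
    lparpError("index", "LL index must match LD's lncRNA index")
  if (!is.null(DD) && !identical(rownames(DD), colnames(LD)))
    lparpError("index", "DD index must match LD's disease index")

  GL <- gipSimilarity(LD, "lncRNA", gip)
  GD <- gipSimilarity(LD, "disease", gip)
  LLf <- integrateSimilarity(LL, GL)
  DDf <- integrateSimilarity(DD, GD)

  LLn <- normalizeSimilarity(LLf, propagation@normalization)
  DDn <- normalizeSimilarity(DDf, propagation@normalization)
  FL <- propagateLabels(LLn, LD@.Data, propagation@alpha,
                        propagation@tol, propagation@maxIter)
  FD <- propagateLabels(DDn, t(LD@.Data), propagation@beta,
                        propagation@tol, propagation@maxIter)
  Fe <- estimatedScore(FL, FD)

  LDpl <- projectLncRNA(LLf, Fe)
  LDpd <- projectDisease(DDf, Fe)
  out <- finalScore(LDpl, LDpd)
  attr(out, "iterations") <- c(lncRNA = attr(FL, "iterations"),
                               disease = attr(FD, "iterations"))
  out
}
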