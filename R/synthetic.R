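.blockLabels <- function(n, nBlocks) {
  sort(rep_len(seq_len(nBlocks), n))
}

.blockSimilarity <- function(labels, ids, simIn, simOut, noiseSd, kind) {
  n <- length(labels)
  S <- matrix(simOut, n, n)
  S[outer(labels, labels, "==")] <- simIn
  if (noiseSd > 0) S <- S + matrix(stats::rnorm(n * n, 0, noiseSd), n, n)
  S <- (S + t(S)) / 2
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  SimilarityMatrix(S, kind = kind)
}

#' Generate a planted co-block lncRNA-disease benchmark
#'
#' lncRNAs and diseases are partitioned into `nBlocks` co-blocks (disease
#' families and the lncRNA groups acting in them). Associations are
#' Bernoulli draws: probability `densityIn` inside a co-block, then
#' `densityOut` outside. Similarities are block-structured (`simIn`
#' within, `simOut` between), perturbed with additive Gaussian noise,
#' symmetrized as `(S + t(S)) / 2`, clipped to \[0, 1\], with unit
#' diagonal. Everything is drawn from one private RNG stream seeded by
#' `config@seed` (draw order: associations, lncRNA similarity noise,
#' disease similarity noise), so outputs are bit-identical for a given
#' configuration; the caller's RNG state is untouched.
#'
#' @param config a [SyntheticConfig-class].
#' @return list with `LD` ([AssociationMatrix-class]), `DD` and `LL`
#'   ([SimilarityMatrix-class], kinds `"semantic"` and `"functional"`),
#'   and `truth` (list of `lncRNABlocks` and `diseaseBlocks` integer
#'   labels).
#' @examples
#' sim <- simulateAssociations(SyntheticConfig(seed = 1))
#' sim$LD
#' @export
simulateAssociations <- function(config = SyntheticConfig()) {
  if (!is(config, "SyntheticConfig"))
    lparpError("config", "config must be a SyntheticConfig")
  lids <- sprintf("L%03d", seq_len(config@nL))
  dids <- sprintf("D%03d", seq_len(config@nD))
  bl <- .blockLabels(config@nL, config@nBlocks)
  bd <- .blockLabels(config@nD, config@nBlocks)
  withLocalSeed(config@seed, {
    p <- matrix(config@densityOut, config@nL, config@nD)
    p[outer(bl, bd, "==")] <- config@densityIn
    ld <- matrix(as.numeric(stats::runif(config@nL * config@nD) < p),
                 config@nL, config@nD, dimnames = list(lids, dids))
    LL <- .blockSimilarity(bl, lids, config@simIn, config@simOut,
                           config@noiseSd, "functional")
    DD <- .blockSimilarity(bd, dids, config@simIn, config@simOut,
                           config@noiseSd, "semantic")
    list(LD = AssociationMatrix(ld), DD = DD, LL = LL,
         truth = list(lncRNABlocks = stats::setNames(bl, lids),
                      diseaseBlocks = stats::setNames(bd, dids)))
  })
}

#' Perfectly separable benchmark instance
#'
#' Deterministic fixture on which the full pipeline provably ranks every
#' held-out true pair above every negative, so leave-one-out
#' cross-validation attains AUC exactly 1. lncRNAs and diseases are split
#' into disjoint co-blocks of at least two members per side, every
#' within-block pair is a known association, similarities are exactly 1
#' within a block and 0 between. Removing any one association leaves the
#' held-out pair's row and column with same-block support, so the score
#' of the held-out cell stays in the within-block score regime while all
#' negatives (between-block cells) only receive the weak GIP-fallback
#' leakage. Blocks of size one would lose that support (the held-out
#' pair's row and column go empty and its score drops into the negative
#' regime), hence the minimum size of 4 per side.
#'
#' @param nL,nD numbers of lncRNAs and diseases, both at least 4.
#' @return list with `LD`, `DD`, `LL` and `truth` as in
#'   [simulateAssociations()].
#' @export
separableInstance <- function(nL, nD) {
  nL <- as.integer(nL); nD <- as.integer(nD)
  if (nL < 4L || nD < 4L)
    lparpError("config", "separableInstance needs nL >= 4 and nD >= 4")
  nBlocks <- min(nL %/% 2L, nD %/% 2L)
  lids <- sprintf("L%03d", seq_len(nL))
  dids <- sprintf("D%03d", seq_len(nD))
  bl <- .blockLabels(nL, nBlocks)
  bd <- .blockLabels(nD, nBlocks)
  ld <- matrix(as.numeric(outer(bl, bd, "==")), nL, nD,
               dimnames = list(lids, dids))
  LL <- .blockSimilarity(bl, lids, 1, 0, 0, "functional")
  DD <- .blockSimilarity(bd, dids, 1, 0, 0, "semantic")
  list(LD = AssociationMatrix(ld), DD = DD, LL = LL,
       truth = list(lncRNABlocks = stats::setNames(bl, lids),
                    diseaseBlocks = stats::setNames(bd, dids)))
}
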