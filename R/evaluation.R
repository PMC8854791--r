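#' ROC curve and AUC from positive and negative score lists
#'
#' Threshold sweep over the union of observed scores (ties grouped), with
#' trapezoidal area. The resulting AUC equals the Mann-Whitney statistic
#' `(#\{pos > neg\} + 0.5 * #\{pos = neg\}) / (n_pos * n_neg)`.
#'
#' @param pos,neg numeric vectors of positive and negative scores (both
#'   nonempty, finite).
#' @return list with `rocPoints` (data frame of `fpr`, `tpr` from (0,0)
#'   to (1,1)) and `auc`.
#' @examples
#' rocAuc(c(3, 1), c(2, 0))$auc  # 0.75
#' @export
rocAuc <- function(pos, neg) {
  if (length(pos) == 0L || length(neg) == 0L)
    lparpError("protocol", "both positive and negative score lists must be nonempty")
  if (!all(is.finite(pos)) || !all(is.finite(neg)))
    lparpError("domain", "scores must be finite")
  np <- length(pos); nn <- length(neg)
  s <- c(pos, neg)
  lab <- c(rep(1L, np), rep(0L, nn))
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; lab <- lab[ord]
  last <- c(which(diff(s) != 0), length(s))  # last index of each tie group
  tpr <- c(0, cumsum(lab)[last] / np)
  fpr <- c(0, cumsum(1L - lab)[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(rocPoints = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

## Fast U-statistic AUC via midranks; used for permutation nulls.
.aucFromRanks <- function(ranks, posIdx, np, nn) {
  (sum(ranks[posIdx]) - np * (np + 1) / 2) / (np * nn)
}

#' Permutation null for an observed AUC
#'
#' Shuffles the positive/negative labels of the pooled scores `nPerm`
#' times and recomputes the AUC each time, giving a Monte-Carlo null
#' distribution and the one-sided p-value
#' `(1 + #\{perm >= observed\}) / (nPerm + 1)`.
#'
#' @param pos,neg pooled positive and negative scores.
#' @param nPerm number of label permutations; default 200.
#' @param seed integer seed for the private RNG stream.
#' @return list with `observed`, `permAuc` (length `nPerm`), `pValue`.
#' @export
aucPermutationTest <- function(pos, neg, nPerm = 200L, seed = 1L) {
  np <- length(pos); nn <- length(neg)
  scores <- c(pos, neg)
  ranks <- rank(scores)  # midranks: ties count half
  observed <- .aucFromRanks(ranks, seq_len(np), np, nn)
  permAuc <- withLocalSeed(seed, {
    vapply(seq_len(nPerm), function(k) {
      .aucFromRanks(ranks, sample.int(np + nn, np), np, nn)
    }, numeric(1L))
  })
  list(observed = observed, permAuc = permAuc,
       pValue = (1 + sum(permAuc >= observed)) / (nPerm + 1))
}

## Per-fold similarity inputs under the leakage policy. When the user
## supplies LL it is passed through unchanged; when LL is absent but DD is
## present, the functional similarity is derived from the *training* LD of
## the fold, so the held-out cell can never inform the training model.
.foldSimilarities <- function(LDtrain, DD, LL, gip, gipRefresh, fullGip) {
  if (gipRefresh == "fold") {
    GL <- gipSimilarity(LDtrain, "lncRNA", gip)
    GD <- gipSimilarity(LDtrain, "disease", gip)
  } else {
    GL <- fullGip$GL
    GD <- fullGip$GD
  }
  LLuse <- if (is.null(LL) && !is.null(DD)) functionalSimilarity(DD, LDtrain) else LL
  list(LLf = integrateSimilarity(LLuse, GL),
       DDf = integrateSimilarity(DD, GD))
}

## Core of lparpPredict once integrated similarities are fixed.
.predictFromIntegrated <- function(LDtrain, LLf, DDf, propagation) {
  LLn <- normalizeSimilarity(LLf, propagation@normalization)
  DDn <- normalizeSimilarity(DDf, propagation@normalization)
  FL <- propagateLabels(LLn, LDtrain@.Data, propagation@alpha,
                        propagation@tol, propagation@maxIter)
  FD <- propagateLabels(DDn, t(LDtrain@.Data), propagation@beta,
                        propagation@tol, propagation@maxIter)
  Fe <- estimatedScore(FL, FD)
  finalScore(projectLncRNA(LLf, Fe), projectDisease(DDf, Fe))@.Data
}

.fullGipOrNull <- function(LD, gip, gipRefresh) {
  if (gipRefresh == "full")
    list(GL = gipSimilarity(LD, "lncRNA", gip),
         GD = gipSimilarity(LD, "disease", gip))
  else NULL
}

#' Leave-one-out cross-validation over known associations
#'
#' Each known pair in turn is removed from `LD`, the fold similarities
#' are recomputed from the training matrix (see `gipRefresh`), the model
#' is refit and the held-out pair's score recorded. Negatives are the
#' pairs unknown in the *full* matrix, scored in the same fold as the
#' held-out positive; positives and negatives are pooled over all folds
#' into one ROC curve (`pooling = "global"`), or restricted to the
#' held-out pair's disease column (`pooling = "per_disease"`).
#'
#' @param LD an [AssociationMatrix-class] with at least two associations.
#' @param DD,LL optional similarity inputs as in [lparpPredict()]. When
#'   `LL` is `NULL` and `DD` is given, the lncRNA functional similarity is
#'   derived from each fold's training matrix.
#' @param propagation a [PropagationParams-class].
#' @param gip a [GipParams-class].
#' @param gipRefresh `"fold"` (default: GIP kernels recomputed from the
#'   training matrix of every fold, so the held-out label never leaks into
#'   training similarities) or `"full"` (computed once from the full
#'   matrix, for reproduction attempts against published protocols that
#'   may have done so).
#' @param pooling `"global"` or `"per_disease"` negative set.
#' @return a [CVResult-class] with protocol `"loocv"`.
#' @export
lparpLOOCV <- function(LD, DD = NULL, LL = NULL,
                       propagation = PropagationParams(),
                       gip = GipParams(),
                       gipRefresh = c("fold", "full"),
                       pooling = c("global", "per_disease")) {
  gipRefresh <- match.arg(gipRefresh)
  pooling <- match.arg(pooling)
  stopifnot(is(LD, "AssociationMatrix"))
  ldm <- LD@.Data
  positives <- which(ldm == 1, arr.ind = TRUE)
  if (nrow(positives) < 2L)
    lparpError("protocol", "LOOCV needs at least two known associations")
  fullGip <- .fullGipOrNull(LD, gip, gipRefresh)

  posScores <- numeric(nrow(positives))
  negScores <- vector("list", nrow(positives))
  ranks <- integer(nrow(positives))
  for (k in seq_len(nrow(positives))) {
    i <- positives[k, 1L]; j <- positives[k, 2L]
    trainM <- ldm
    trainM[i, j] <- 0
    LDtrain <- AssociationMatrix(trainM)
    sims <- .foldSimilarities(LDtrain, DD, LL, gip, gipRefresh, fullGip)
    sc <- .predictFromIntegrated(LDtrain, sims$LLf, sims$DDf, propagation)
    posScores[k] <- sc[i, j]
    neg <- if (pooling == "global") sc[ldm == 0] else sc[ldm[, j] == 0, j]
    negScores[[k]] <- neg
    ranks[k] <- 1L + sum(neg > posScores[k])
  }
  negAll <- unlist(negScores, use.names = FALSE)
  roc <- rocAuc(posScores, negAll)
  new("CVResult", protocol = "loocv",
      foldScores = data.frame(
        lncRNA = rownames(ldm)[positives[, 1L]],
        disease = colnames(ldm)[positives[, 2L]],
        score = posScores, rank = ranks,
        nNeg = lengths(negScores)),
      rocPoints = roc$rocPoints, auc = roc$auc,
      posScores = posScores, negScores = negAll)
}

#' Holdout cross-validation for new lncRNAs and isolated diseases
#'
#' Simulates prediction for entities with no training associations. In
#' `"new_lncRNA"` mode, each lncRNA with at least one known association is
#' held out by zeroing its whole `LD` row; the model is refit and the
#' lncRNA's true pairs are ranked against that row's unknown pairs.
#' `"isolated_disease"` does the same per disease column. ROC/AUC are
#' pooled over all held-out entities.
#'
#' @inheritParams lparpLOOCV
#' @param mode `"new_lncRNA"` or `"isolated_disease"`.
#' @return a [CVResult-class] with the chosen protocol.
#' @export
lparpHoldoutCV <- function(LD, DD = NULL, LL = NULL,
                           propagation = PropagationParams(),
                           gip = GipParams(),
                           mode = c("new_lncRNA", "isolated_disease"),
                           gipRefresh = c("fold", "full")) {
  mode <- match.arg(mode)
  gipRefresh <- match.arg(gipRefresh)
  stopifnot(is(LD, "AssociationMatrix"))
  ldm <- LD@.Data
  byRow <- mode == "new_lncRNA"
  entityTotals <- if (byRow) rowSums(ldm) else colSums(ldm)
  held <- which(entityTotals >= 1)
  if (length(held) < 1L || sum(ldm) <= max(entityTotals))
    lparpError("protocol",
      "holdout CV needs associations left in training after removing any one entity")
  fullGip <- .fullGipOrNull(LD, gip, gipRefresh)

  folds <- lapply(held, function(e) {
    trainM <- ldm
    if (byRow) trainM[e, ] <- 0 else trainM[, e] <- 0
    LDtrain <- AssociationMatrix(trainM)
    sims <- .foldSimilarities(LDtrain, DD, LL, gip, gipRefresh, fullGip)
    sc <- .predictFromIntegrated(LDtrain, sims$LLf, sims$DDf, propagation)
    entityScores <- if (byRow) sc[e, ] else sc[, e]
    truth <- if (byRow) ldm[e, ] else ldm[, e]
    pos <- entityScores[truth == 1]
    neg <- entityScores[truth == 0]
    rk <- vapply(pos, function(p) 1L + sum(neg > p), integer(1L))
    list(pos = pos, neg = neg,
         df = data.frame(
           lncRNA = if (byRow) rownames(ldm)[e] else names(pos),
           disease = if (byRow) names(pos) else colnames(ldm)[e],
           score = unname(pos), rank = rk, nNeg = length(neg)))
  })
  posAll <- unlist(lapply(folds, `[[`, "pos"), use.names = FALSE)
  negAll <- unlist(lapply(folds, `[[`, "neg"), use.names = FALSE)
  roc <- rocAuc(posAll, negAll)
  new("CVResult", protocol = mode,
      foldScores = do.call(rbind, lapply(folds, `[[`, "df")),
      rocPoints = roc$rocPoints, auc = roc$auc,
      posScores = posAll, negScores = negAll)
}

#' Retention-parameter sweep under LOOCV
#'
#' Runs [lparpLOOCV()] for every value in `alphas`, setting the disease-
#' side retention `beta` equal to `alpha` (the two are tied during
#' selection), and tabulates the AUC. The default grid steps from 0 to 1
#' by 0.1.
#'
#' @inheritParams lparpLOOCV
#' @param alphas numeric vector of retention values in \[0, 1\].
#' @return data frame with columns `alpha`, `auc`; attribute `"best"`
#'   holds the alpha with the largest AUC (first on ties).
#' @export
parameterSweep <- function(LD, DD = NULL, LL = NULL,
                           alphas = seq(0, 1, by = 0.1),
                           propagation = PropagationParams(),
                           gip = GipParams(),
                           gipRefresh = c("fold", "full")) {
  gipRefresh <- match.arg(gipRefresh)
  if (any(alphas < 0 | alphas > 1))
    lparpError("domain", "alphas must lie in [0, 1]")
  aucs <- vapply(alphas, function(a) {
    p <- PropagationParams(alpha = a, beta = a, tol = propagation@tol,
                           maxIter = propagation@maxIter,
                           normalization = propagation@normalization)
    lparpLOOCV(LD, DD, LL, p, gip, gipRefresh)@auc
  }, numeric(1L))
  out <- data.frame(alpha = alphas, auc = aucs)
  attr(out, "best") <- alphas[which.max(aucs)]
  out
}
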