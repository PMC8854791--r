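test_that("rocAuc equals the pairwise Mann-Whitney count, ties counted half", {
  expect_equal(rocAuc(2, 1)$auc, 1)
  expect_equal(rocAuc(1, 1)$auc, 0.5)
  expect_equal(rocAuc(c(3, 1), c(2, 0))$auc, 0.75)

  withr::local_seed(81)
  for (rep in 1:20) {
    ## scores drawn from a small grid so ties actually occur
    pos <- sample(seq(0, 1, by = 0.1), sample(2:15, 1), replace = TRUE)
    neg <- sample(seq(0, 1, by = 0.1), sample(2:25, 1), replace = TRUE)
    got <- rocAuc(pos, neg)
    expect_equal(got$auc, naiveAuc(pos, neg), tolerance = 1e-12)
    ## ROC curve is a monotone path from (0,0) to (1,1)
    rp <- got$rocPoints
    expect_equal(rp$fpr[1], 0); expect_equal(rp$tpr[1], 0)
    expect_equal(rp$fpr[nrow(rp)], 1); expect_equal(rp$tpr[nrow(rp)], 1)
    expect_false(is.unsorted(rp$fpr) || is.unsorted(rp$tpr))
    ## AUC is invariant under strictly monotone score transforms
    expect_equal(rocAuc(exp(2 * pos), exp(2 * neg))$auc, got$auc,
                 tolerance = 1e-12)
  }
  expect_error(rocAuc(numeric(0), 1), class = "lparp_protocol_error")
})

test_that("rocAuc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(82)
  pos <- rnorm(30, 1); neg <- rnorm(50)
  ours <- rocAuc(pos, neg)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 30), rep(0, 50)), predictor = c(pos, neg),
    quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("LOOCV is perfect on the separable instance and null under shuffling", {
  sep <- separableInstance(8, 8)
  cv <- lparpLOOCV(sep$LD, sep$DD, sep$LL)
  expect_identical(cv@protocol, "loocv")
  expect_equal(cv@auc, 1)
  expect_true(all(foldScores(cv)$rank == 1L))

  perm <- aucPermutationTest(cv@posScores, cv@negScores, nPerm = 200,
                             seed = 3)
  expect_lt(abs(mean(perm$permAuc) - 0.5), 0.05)
})

test_that("LOOCV refuses degenerate inputs", {
  expect_error(lparpLOOCV(mkAssoc(matrix(c(1, 0, 0, 0), 2, 2))),
               class = "lparp_protocol_error")
})

test_that("LOOCV equals the naive end-to-end transcription on a small instance", {
  sim <- simulateAssociations(SyntheticConfig(nL = 12, nD = 8, nBlocks = 2,
                                              seed = 7))
  cv <- lparpLOOCV(sim$LD, sim$DD, sim$LL)
  expect_equal(cv@auc,
               naiveLoocv(sim$LD@.Data, sim$DD@.Data, sim$LL@.Data),
               tolerance = 1e-12)
  ## fold bookkeeping: one fold per known pair, ranks consistent with scores
  expect_equal(nrow(foldScores(cv)), sum(sim$LD@.Data))
  expect_true(all(foldScores(cv)$rank >= 1L))
})

test_that("the held-out cell never leaks into the training-fold model", {
  sim <- simulateAssociations(SyntheticConfig(nL = 8, nD = 6, nBlocks = 2,
                                              seed = 9))
  ldm <- sim$LD@.Data
  pos <- which(ldm == 1, arr.ind = TRUE)
  i <- pos[1, 1]; j <- pos[1, 2]
  ## the fold's training matrix is LD with the held-out cell zeroed, so the
  ## fold model must be identical whether or not the full matrix had that 1
  train <- ldm; train[i, j] <- 0
  LDtrain <- AssociationMatrix(train)
  simsA <- lparp:::.foldSimilarities(LDtrain, sim$DD, sim$LL, GipParams(),
                                     "fold", NULL)
  scA <- lparp:::.predictFromIntegrated(LDtrain, simsA$LLf, simsA$DDf,
                                        PropagationParams())
  ## under gipRefresh = "full" the kernels would differ; under "fold" the
  ## training model depends only on the training matrix
  expect_identical(simsA$LLf@.Data,
                   integrateSimilarity(sim$LL,
                     gipSimilarity(LDtrain, "lncRNA"))@.Data)
  cv <- lparpLOOCV(sim$LD, sim$DD, sim$LL)
  k <- which(foldScores(cv)$lncRNA == rownames(ldm)[i] &
             foldScores(cv)$disease == colnames(ldm)[j])
  expect_equal(foldScores(cv)$score[k], scA[i, j], tolerance = 1e-14)
})

test_that("holdout CV ranks held-out entities by similarity support", {
  ## two lncRNAs share a block and diseases; a held-out lncRNA's true
  ## pairs must outrank unrelated pairs through its similar partner
  sep <- separableInstance(8, 8)
  hn <- lparpHoldoutCV(sep$LD, sep$DD, sep$LL, mode = "new_lncRNA")
  expect_identical(hn@protocol, "new_lncRNA")
  expect_equal(hn@auc, 1)
  hi <- lparpHoldoutCV(sep$LD, sep$DD, sep$LL, mode = "isolated_disease")
  expect_identical(hi@protocol, "isolated_disease")
  expect_equal(hi@auc, 1)
  expect_true(all(is.finite(hn@posScores)) && all(is.finite(hn@negScores)))
})

test_that("per-disease pooling restricts negatives to the held-out column", {
  sim <- simulateAssociations(SyntheticConfig(nL = 10, nD = 6, nBlocks = 2,
                                              seed = 13))
  cvg <- lparpLOOCV(sim$LD, sim$DD, sim$LL, pooling = "global")
  cvd <- lparpLOOCV(sim$LD, sim$DD, sim$LL, pooling = "per_disease")
  nneg <- colSums(sim$LD@.Data == 0)
  expect_equal(foldScores(cvd)$nNeg,
               unname(nneg[foldScores(cvd)$disease]))
  expect_gt(length(cvg@negScores), length(cvd@negScores))
})

test_that("parameter sweep tabulates AUC per retention value deterministically", {
  sim <- simulateAssociations(SyntheticConfig(nL = 10, nD = 6, nBlocks = 2,
                                              seed = 13))
  one <- parameterSweep(sim$LD, sim$DD, sim$LL, alphas = 0)
  expect_equal(nrow(one), 1L)
  expect_equal(one$alpha, 0)

  tab1 <- parameterSweep(sim$LD, sim$DD, sim$LL, alphas = c(0.3, 0.9))
  tab2 <- parameterSweep(sim$LD, sim$DD, sim$LL, alphas = c(0.3, 0.9))
  expect_identical(tab1, tab2)  # bit-for-bit reproducible
  expect_true(attr(tab1, "best") %in% tab1$alpha)
  expect_equal(tab1$auc[tab1$alpha == 0.9],
               lparpLOOCV(sim$LD, sim$DD, sim$LL)@auc)
  expect_error(parameterSweep(sim$LD, alphas = c(-0.1)),
               class = "lparp_domain_error")
})
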