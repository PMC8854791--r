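test_that("GIP kernel matches hand-derived values and conventions", {
  LD <- mkAssoc(matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE))
  G <- gipSimilarity(LD, "lncRNA")
  expect_equal(G@.Data[1, 2], exp(-2 / 3), tolerance = 1e-12)
  expect_identical(diag(G@.Data), c(L1 = 1, L2 = 1))
  expect_identical(simKind(G), "gip")

  ## orthogonal unit profiles
  Gd <- gipSimilarity(mkAssoc(diag(2)), "lncRNA")
  expect_equal(Gd@.Data[1, 2], exp(-2), tolerance = 1e-12)

  ## identical profiles have similarity exactly 1
  LD3 <- mkAssoc(matrix(c(1, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE))
  expect_equal(gipSimilarity(LD3, "lncRNA")@.Data[1, 2], 1)

  ## bandwidth constant scales the exponent
  G2 <- gipSimilarity(LD, "lncRNA", GipParams(gammaPrime = 2))
  expect_equal(G2@.Data[1, 2], exp(-4 / 3), tolerance = 1e-12)

  expect_error(gipSimilarity(mkAssoc(matrix(0, 2, 2)), "disease"),
               class = "lparp_degenerate_input_error")
  expect_error(gipSimilarity(mkAssoc(matrix(0, 2, 2)), "disease"),
               regexp = "disease")
})

test_that("GIP kernel agrees with the brute-force oracle and is permutation-equivariant", {
  withr::local_seed(21)
  for (rep in 1:10) {
    LD <- randAssoc(7, 5, p = 0.35)
    for (axis in c("lncRNA", "disease")) {
      G <- gipSimilarity(LD, axis)@.Data
      P <- if (axis == "lncRNA") LD@.Data else t(LD@.Data)
      expect_equal(unname(G), naiveGip(P), tolerance = 1e-12)
      expect_lt(max(abs(G - t(G))), 1e-12)
      expect_true(all(G > 0 & G <= 1))
    }
    ## relabeling rows permutes the kernel identically
    perm <- sample(nrow(LD@.Data))
    Gp <- gipSimilarity(AssociationMatrix(LD@.Data[perm, ]), "lncRNA")@.Data
    G0 <- gipSimilarity(LD, "lncRNA")@.Data
    expect_equal(unname(Gp), unname(G0[perm, perm]), tolerance = 1e-14)
  }
})

test_that("semantic similarity reproduces the decay recursion", {
  chain <- DiseaseDAG(data.frame(child = "B", parent = "A"))
  S <- semanticSimilarity(chain, c("B", "A"), delta = 0.5)
  expect_equal(S@.Data["B", "A"], 0.6, tolerance = 1e-12)
  expect_equal(diag(S@.Data), c(B = 1, A = 1))

  ## disjoint ancestor closures share no terms
  forest <- DiseaseDAG(data.frame(child = c("B", "D"), parent = c("A", "C")))
  S2 <- semanticSimilarity(forest, c("B", "D"))
  expect_equal(S2@.Data["B", "D"], 0)

  ## diamond: best path wins, not the sum of paths
  diamond <- DiseaseDAG(data.frame(child = c("D", "D", "B", "C"),
                                   parent = c("B", "C", "A", "A")))
  S3 <- semanticSimilarity(diamond, c("D", "A"), delta = 0.5)
  ## D's closure: D=1, B=C=0.5, A=max(0.25, 0.25)=0.25; DV(D)=2.25
  expect_equal(S3@.Data["D", "A"], (0.25 + 1) / (2.25 + 1), tolerance = 1e-12)

  expect_error(semanticSimilarity(chain, c("B", "ZZ")),
               class = "lparp_index_error")
})

test_that("semantic similarity equals all-paths enumeration on random DAGs", {
  withr::local_seed(31)
  for (rep in 1:12) {
    n <- sample(3:8, 1)
    edges <- randDagEdges(n)
    dag <- DiseaseDAG(edges)
    targets <- sample(dagNodes(dag), min(4, n))
    delta <- runif(1, 0.2, 0.9)
    S <- semanticSimilarity(dag, targets, delta)@.Data
    expect_equal(unname(S), unname(naiveSemantic(edges, targets, delta)),
                 tolerance = 1e-12)
  }
})

test_that("functional similarity follows the max-average construction", {
  DD <- mkSim(matrix(c(1, 0.6, 0.6, 1), 2, 2), "semantic",
              ids = c("D1", "D2"))
  ## identical nonempty disease sets
  LDsame <- mkAssoc(matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE))
  expect_equal(functionalSimilarity(DD, LDsame)@.Data[1, 2], 1)

  ## one lncRNA unannotated -> 0 off-diagonal, diagonal still 1
  LDempty <- mkAssoc(matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE))
  Fe <- functionalSimilarity(DD, LDempty)@.Data
  expect_equal(Fe[1, 2], 0)
  expect_equal(diag(Fe), c(L1 = 1, L2 = 1))

  ## singleton sets {d1}, {d2}: (0.6 + 0.6) / 2
  LDsplit <- mkAssoc(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(functionalSimilarity(DD, LDsplit)@.Data[1, 2], 0.6,
               tolerance = 1e-12)

  withr::local_seed(41)
  for (rep in 1:8) {
    LD <- randAssoc(6, 5, p = 0.4)
    A <- matrix(runif(25), 5, 5)
    S <- (A + t(A)) / 2
    diag(S) <- 1
    DDr <- mkSim(S, "semantic", ids = diseaseNames(LD))
    got <- functionalSimilarity(DDr, LD)@.Data
    expect_equal(unname(got), naiveFunctional(DDr@.Data, LD@.Data),
                 tolerance = 1e-12)
    expect_lt(max(abs(got - t(got))), 1e-12)
  }
})

test_that("integration keeps nonzero primary entries and falls back to GIP", {
  ids <- c("a", "b")
  gip <- mkSim(matrix(c(1, 0.3, 0.3, 1), 2, 2), "gip", ids)
  zero <- mkSim(matrix(0, 2, 2), "functional", ids)
  expect_equal(integrateSimilarity(zero, gip)@.Data, gip@.Data)
  prim <- mkSim(matrix(c(1, 0.4, 0.4, 1), 2, 2), "functional", ids)
  out <- integrateSimilarity(prim, gip)@.Data
  expect_equal(out[1, 2], 0.4)
  ident <- mkSim(diag(2), "functional", ids)
  expect_equal(integrateSimilarity(ident, gip)@.Data, gip@.Data)
  expect_identical(simKind(integrateSimilarity(prim, gip)), "integrated")
  expect_error(integrateSimilarity(mkSim(diag(3)), gip),
               class = "lparp_dimension_error")
})
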