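#' Gaussian interaction-profile kernel similarity
#'
#' Computes the GIP kernel over one side of the bipartite association
#' matrix. The interaction profile of lncRNA i is row i of `LD` (for
#' `axis = "lncRNA"`); the profile of disease j is column j (for
#' `axis = "disease"`). Similarity between two nodes is
#' `exp(-gamma * ||p_i - p_j||^2)` with bandwidth
#' `gamma = gammaPrime / mean_i ||p_i||^2`, so that the kernel width
#' adapts to the overall density of the catalogue.
#'
#' @param LD an [AssociationMatrix-class].
#' @param axis `"lncRNA"` or `"disease"`: which node set to compare.
#' @param params a [GipParams-class]; default bandwidth constant 1.
#' @return a [SimilarityMatrix-class] of kind `"gip"`: symmetric, unit
#'   diagonal, entries in (0, 1].
#' @examples
#' LD <- AssociationMatrix(matrix(c(1, 1, 0, 1), 2, 2,
#'   dimnames = list(c("L1", "L2"), c("D1", "D2"))))
#' gipSimilarity(LD, "lncRNA")
#' @export
gipSimilarity <- function(LD, axis = c("lncRNA", "disease"),
                          params = GipParams()) {
  axis <- match.arg(axis)
  stopifnot(is(LD, "AssociationMatrix"), is(params, "GipParams"))
  P <- if (axis == "lncRNA") LD@.Data else t(LD@.Data)
  sq <- rowSums(P^2)
  msq <- mean(sq)
  if (msq == 0)
    lparpError("degenerate_input",
      sprintf("all %s interaction profiles are zero; GIP bandwidth undefined",
              axis))
  gamma <- params@gammaPrime / msq
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0  # numeric round-off
  S <- exp(-gamma * d2)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  SimilarityMatrix(S, kind = "gip")
}

## D-value vector of one term: contribution of every ancestor of `target`
## (including itself) under the decay-recursion, computed in topological
## order of the ancestor closure. Edges point child -> parent.
.dValues <- function(g, target, delta) {
  anc <- igraph::subcomponent(g, target, mode = "out")
  sub <- igraph::induced_subgraph(g, anc)
  ord <- igraph::topo_sort(sub, mode = "out")
  nm <- igraph::V(sub)$name[as.integer(ord)]
  D <- stats::setNames(numeric(length(nm)), nm)
  D[target] <- 1
  for (t in nm) {
    if (t == target) next
    ch <- igraph::V(sub)$name[as.integer(igraph::neighbors(sub, t, mode = "in"))]
    D[t] <- delta * max(D[ch])
  }
  D
}

#' DAG-based disease semantic similarity (Wang's method)
#'
#' Each disease is a term in a directed acyclic graph; its semantic value
#' spreads to ancestors with geometric decay `delta` per edge, taking the
#' best path where several exist: `D_i(i) = 1` and
#' `D_i(t) = delta * max D_i(t')` over children `t'` of `t` inside the
#' ancestor closure of `i`. With `DV(i) = sum_t D_i(t)`, similarity is
#' `DD(i, j) = sum_{t in T_i & T_j} (D_i(t) + D_j(t)) / (DV(i) + DV(j))`.
#' Diseases sharing no ancestors get similarity 0; the diagonal is 1.
#'
#' @param dag a [DiseaseDAG-class].
#' @param targets character vector of disease term identifiers (must be
#'   DAG nodes); defines the result's index order.
#' @param delta decay factor in (0, 1]; default 0.5, the standard choice
#'   in the disease-ontology literature.
#' @return a [SimilarityMatrix-class] of kind `"semantic"`.
#' @export
semanticSimilarity <- function(dag, targets, delta = 0.5) {
  stopifnot(is(dag, "DiseaseDAG"))
  if (!(delta > 0 && delta <= 1))
    lparpError("domain", "delta must be in (0, 1]")
  targets <- as.character(targets)
  absent <- setdiff(targets, dagNodes(dag))
  if (length(absent))
    lparpError("index", sprintf("term(s) not in DAG: %s",
                                paste(absent, collapse = ", ")))
  dv <- lapply(targets, function(t) .dValues(dag@graph, t, delta))
  names(dv) <- targets
  n <- length(targets)
  S <- diag(1, n)
  dimnames(S) <- list(targets, targets)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      Di <- dv[[i]]; Dj <- dv[[j]]
      shared <- intersect(names(Di), names(Dj))
      S[i, j] <- S[j, i] <- if (length(shared))
        sum(Di[shared] + Dj[shared]) / (sum(Di) + sum(Dj)) else 0
    }
  }
  SimilarityMatrix(S, kind = "semantic")
}

#' lncRNA functional similarity from associated-disease sets
#'
#' Max-average construction: with `D_i` the set of diseases associated
#' with lncRNA i and `DD` a disease similarity matrix,
#' `LL(i, j) = (sum_{d in D_i} max_{d' in D_j} DD(d, d') +
#'              sum_{d in D_j} max_{d' in D_i} DD(d, d')) / (|D_i| + |D_j|)`.
#' Pairs where either lncRNA is unannotated get 0; the diagonal is forced
#' to 1 (self-similarity, and it keeps unannotated lncRNAs from having an
#' all-zero row in propagation).
#'
#' @param DD a [SimilarityMatrix-class] over diseases, indexed like the
#'   columns of `LD`.
#' @param LD an [AssociationMatrix-class].
#' @return a [SimilarityMatrix-class] of kind `"functional"` over lncRNAs.
#' @export
functionalSimilarity <- function(DD, LD) {
  stopifnot(is(DD, "SimilarityMatrix"), is(LD, "AssociationMatrix"))
  if (!identical(rownames(DD), colnames(LD)))
    lparpError("index", "disease similarity index must match LD's disease index")
  ddm <- DD@.Data
  ldm <- LD@.Data
  nl <- nrow(ldm)
  sets <- lapply(seq_len(nl), function(i) which(ldm[i, ] == 1))
  sizes <- lengths(sets)
  ## best[i, d] = max similarity between disease d and lncRNA i's disease set
  best <- matrix(0, nl, ncol(ldm))
  nonempty <- which(sizes > 0L)
  for (i in nonempty)
    best[i, ] <- apply(ddm[sets[[i]], , drop = FALSE], 2L, max)
  S <- matrix(0, nl, nl, dimnames = list(rownames(ldm), rownames(ldm)))
  for (i in nonempty) for (j in nonempty) {
    if (j < i) next
    S[i, j] <- S[j, i] <-
      (sum(best[i, sets[[j]]]) + sum(best[j, sets[[i]]])) / (sizes[i] + sizes[j])
  }
  diag(S) <- 1
  SimilarityMatrix(S, kind = "functional")
}

#' Integrate a primary similarity with its GIP fallback
#'
#' Elementwise: keep the primary (semantic or functional) similarity
#' wherever it is nonzero, and fall back to the GIP kernel similarity
#' where it is exactly zero. The zero test is exact (`== 0`), since both
#' inputs are constructed values rather than measurements.
#'
#' @param primary a [SimilarityMatrix-class] (semantic or functional), or
#'   `NULL` to use the GIP similarity everywhere.
#' @param gip a [SimilarityMatrix-class] of the same shape and index.
#' @return a [SimilarityMatrix-class] of kind `"integrated"`.
#' @export
integrateSimilarity <- function(primary, gip) {
  stopifnot(is(gip, "SimilarityMatrix"))
  if (is.null(primary))
    return(SimilarityMatrix(gip@.Data, kind = "integrated"))
  stopifnot(is(primary, "SimilarityMatrix"))
  if (!identical(dim(primary), dim(gip)))
    lparpError("dimension", "primary and GIP similarity shapes differ")
  if (!identical(rownames(primary), rownames(gip)))
    lparpError("index", "primary and GIP similarity indices differ")
  out <- ifelse(primary@.Data != 0, primary@.Data, gip@.Data)
  dimnames(out) <- dimnames(gip@.Data)
  SimilarityMatrix(out, kind = "integrated")
}
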