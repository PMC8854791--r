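#' Binary lncRNA-disease association matrix
#'
#' An `n_l x n_d` Boolean incidence matrix `LD` with `LD[i, j] = 1` when
#' lncRNA `i` has a known association with disease `j`. Row names are the
#' lncRNA identifiers and column names the disease identifiers; identifier
#' matching throughout the package is exact-string and case-sensitive, and
#' the index of an identifier is stable for the lifetime of a run.
#'
#' @slot .Data numeric matrix with entries in \{0, 1\}.
#' @seealso [readAssociations()], [lncRNANames()], [diseaseNames()]
#' @export
setClass("AssociationMatrix", contains = "matrix")

setValidity("AssociationMatrix", function(object) {
  m <- object@.Data
  if (!is.numeric(m)) return("association matrix must be numeric")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("association matrix must carry lncRNA row names and disease column names")
  if (anyDuplicated(rownames(m))) return("duplicate lncRNA identifiers")
  if (anyDuplicated(colnames(m))) return("duplicate disease identifiers")
  if (!all(m %in% c(0, 1))) return("entries must all be 0 or 1")
  TRUE
})

#' @param values numeric matrix of 0/1 entries with row (lncRNA) and
#'   column (disease) names.
#' @rdname AssociationMatrix-class
#' @export
AssociationMatrix <- function(values) {
  new("AssociationMatrix", as.matrix(values))
}

#' Square similarity matrix over one node set
#'
#' Nonnegative square matrix with matching row/column identifiers. The
#' `kind` tag records the construction: `"semantic"` (disease DAG
#' similarity), `"functional"` (lncRNA functional similarity), `"gip"`
#' (Gaussian interaction-profile kernel), `"integrated"` (primary
#' similarity with GIP fallback) or `"normalized"` (propagation-ready).
#' All kinds except `"normalized"` are required to be symmetric to within
#' 1e-12; `"gip"` additionally has unit diagonal.
#'
#' @slot .Data numeric matrix.
#' @slot kind character scalar, one of the kinds above.
#' @export
setClass("SimilarityMatrix", contains = "matrix",
  representation(kind = "character"))

.SIM_KINDS <- c("semantic", "functional", "gip", "integrated", "normalized")

setValidity("SimilarityMatrix", function(object) {
  m <- object@.Data
  if (!is.numeric(m)) return("similarity matrix must be numeric")
  if (nrow(m) != ncol(m)) return("similarity matrix must be square")
  if (length(object@kind) != 1L || !object@kind %in% .SIM_KINDS)
    return(sprintf("kind must be one of %s", paste(.SIM_KINDS, collapse = ", ")))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("similarity matrix must carry row and column names")
  if (!identical(rownames(m), colnames(m)))
    return("row and column names must be identical")
  if (any(m < 0)) return("similarity entries must be nonnegative")
  if (object@kind != "normalized" && max(abs(m - t(m))) >= 1e-12)
    return("similarity matrix must be symmetric (max |S - t(S)| < 1e-12)")
  if (object@kind == "gip" && any(diag(m) != 1))
    return("GIP similarity must have unit diagonal")
  TRUE
})

#' @param values nonnegative square numeric matrix with identical row and
#'   column names.
#' @param kind character scalar tagging the construction.
#' @rdname SimilarityMatrix-class
#' @export
SimilarityMatrix <- function(values, kind) {
  new("SimilarityMatrix", as.matrix(values), kind = kind)
}

#' Directed acyclic graph of disease terms
#'
#' Holds a term DAG given as (child, parent) edges, used by
#' [semanticSimilarity()]. Acyclicity is enforced at construction.
#'
#' @slot graph an igraph object with edges directed child -> parent.
#' @seealso [readDiseaseDAG()]
#' @export
setClass("DiseaseDAG", representation(graph = "ANY"))

setValidity("DiseaseDAG", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must be an igraph object")
  if (!igraph::is_dag(g)) return("term graph contains a cycle")
  TRUE
})

#' @param edges data frame (or two-column matrix) of child/parent term
#'   identifier pairs.
#' @param nodes optional character vector of node identifiers; defaults to
#'   all identifiers seen in `edges`. Extra isolated terms may be declared
#'   here.
#' @rdname DiseaseDAG-class
#' @export
DiseaseDAG <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L)
    lparpError("format", "DAG edges need a child and a parent column")
  edges <- data.frame(child = as.character(edges[[1L]]),
                      parent = as.character(edges[[2L]]))
  seen <- unique(c(edges$child, edges$parent))
  if (is.null(nodes)) nodes <- seen
  nodes <- as.character(nodes)
  if (!all(seen %in% nodes))
    lparpError("format", "every edge endpoint must be a declared node")
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
    vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g))
    lparpError("acyclicity", "term graph contains a cycle")
  new("DiseaseDAG", graph = g)
}

#' Real-valued prediction score matrix
#'
#' Finite real matrix of association scores with named rows and columns.
#' Orientation is `n_l x n_d` (lncRNA by disease) for estimated and final
#' scores; the disease-side propagation and projection intermediates are
#' `n_d x n_l` and are documented as such where they occur.
#'
#' @slot .Data numeric matrix with all entries finite.
#' @export
setClass("ScoreMatrix", contains = "matrix")

setValidity("ScoreMatrix", function(object) {
  m <- object@.Data
  if (!is.numeric(m)) return("score matrix must be numeric")
  if (!all(is.finite(m))) return("score matrix entries must all be finite")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("score matrix must carry row and column names")
  TRUE
})

#' @param values finite numeric matrix with row and column names.
#' @rdname ScoreMatrix-class
#' @export
ScoreMatrix <- function(values) {
  new("ScoreMatrix", as.matrix(values))
}

#' Cross-validation result
#'
#' Container returned by [lparpLOOCV()] and [lparpHoldoutCV()]: per-fold
#' held-out scores and ranks, pooled ROC points, the area under the ROC
#' curve and the pooled positive/negative score vectors (kept so that
#' permutation nulls can be computed without refitting).
#'
#' @slot protocol one of `"loocv"`, `"new_lncRNA"`, `"isolated_disease"`.
#' @slot foldScores data frame with columns `lncRNA`, `disease`, `score`,
#'   `rank` (competition rank of the held-out score among that fold's
#'   negatives) and `nNeg`.
#' @slot rocPoints data frame of `(fpr, tpr)` points from (0,0) to (1,1).
#' @slot auc area under the ROC curve, in \[0, 1\].
#' @slot posScores,negScores pooled held-out positive and negative scores.
#' @export
setClass("CVResult", representation(
  protocol = "character",
  foldScores = "data.frame",
  rocPoints = "data.frame",
  auc = "numeric",
  posScores = "numeric",
  negScores = "numeric"))

setValidity("CVResult", function(object) {
  if (!object@protocol %in% c("loocv", "new_lncRNA", "isolated_disease"))
    return("unknown protocol")
  if (length(object@auc) != 1L || object@auc < 0 || object@auc > 1)
    return("auc must be a scalar in [0, 1]")
  rp <- object@rocPoints
  if (!all(c("fpr", "tpr") %in% names(rp))) return("rocPoints needs fpr, tpr")
  if (is.unsorted(rp$fpr) || is.unsorted(rp$tpr))
    return("ROC points must be monotone nondecreasing")
  TRUE
})

#' Gaussian interaction-profile kernel parameters
#'
#' The kernel bandwidth on each axis is `gammaPrime` divided by the mean
#' squared profile norm over that axis, so `gammaPrime = 1` (the default,
#' and van Laarhoven's original convention) makes the bandwidth the
#' reciprocal of the mean squared interaction-profile norm.
#'
#' @slot gammaPrime positive numerator bandwidth constant.
#' @export
setClass("GipParams", representation(gammaPrime = "numeric"))

setValidity("GipParams", function(object) {
  if (length(object@gammaPrime) != 1L || !is.finite(object@gammaPrime) ||
      object@gammaPrime <= 0)
    return("gammaPrime must be a positive scalar")
  TRUE
})

#' @param gammaPrime positive numerator bandwidth constant; default 1.
#' @rdname GipParams-class
#' @export
GipParams <- function(gammaPrime = 1) {
  new("GipParams", gammaPrime = as.numeric(gammaPrime))
}

#' Label-propagation parameters
#'
#' `alpha` (lncRNA side) and `beta` (disease side) are the retention
#' rates: the fraction of each node's score received from its neighbours
#' at every step, with `1 - alpha` (resp. `1 - beta`) re-injected from the
#' initial labels. Both default to 0.9, the value selected by leave-one-out
#' cross-validation sweeps on all three lncRNADisease snapshots; they are
#' kept as separate parameters even though the sweep ties them. Iteration
#' stops when the maximum absolute elementwise change drops below `tol`.
#' `normalization` selects how the integrated similarity is normalized
#' before propagation: `"sum"` divides entry (i, j) by rowsum_i + colsum_j
#' (the default reading of the method), `"symmetric"` uses
#' D^-1/2 S D^-1/2.
#'
#' @slot alpha,beta retention rates in \[0, 1\].
#' @slot tol positive convergence threshold on the max-abs update.
#' @slot maxIter maximum number of iterations.
#' @slot normalization `"sum"` or `"symmetric"`.
#' @export
setClass("PropagationParams", representation(
  alpha = "numeric", beta = "numeric", tol = "numeric",
  maxIter = "integer", normalization = "character"))

setValidity("PropagationParams", function(object) {
  for (s in c("alpha", "beta"))
    if (length(slot(object, s)) != 1L || slot(object, s) < 0 || slot(object, s) > 1)
      return(sprintf("%s must be a scalar in [0, 1]", s))
  if (length(object@tol) != 1L || object@tol <= 0)
    return("tol must be a positive scalar")
  if (length(object@maxIter) != 1L || object@maxIter < 1L)
    return("maxIter must be a positive integer")
  if (!object@normalization %in% c("sum", "symmetric"))
    return("normalization must be 'sum' or 'symmetric'")
  TRUE
})

#' @param alpha,beta retention rates in \[0, 1\]; default 0.9.
#' @param tol convergence threshold; default 1e-6.
#' @param maxIter iteration cap; default 1000.
#' @param normalization `"sum"` (default) or `"symmetric"`.
#' @rdname PropagationParams-class
#' @export
PropagationParams <- function(alpha = 0.9, beta = 0.9, tol = 1e-6,
                              maxIter = 1000L, normalization = "sum") {
  new("PropagationParams", alpha = as.numeric(alpha), beta = as.numeric(beta),
      tol = as.numeric(tol), maxIter = as.integer(maxIter),
      normalization = normalization)
}

#' Synthetic benchmark configuration
#'
#' Parameters of the planted co-block generator in
#' [simulateAssociations()]. The defaults emulate a sparse curated
#' association catalogue: 60 lncRNAs by 40 diseases in 4 co-blocks, with
#' within-block association probability 0.25 and background probability
#' 0.01 (overall density about 7%, concentrated in blocks the way curated
#' lncRNA-disease data concentrate in well-studied disease families), and
#' block-structured similarities 0.8 within / 0.1 between blocks with
#' Gaussian noise (sd 0.05).
#'
#' @slot nL,nD numbers of lncRNAs and diseases.
#' @slot nBlocks number of planted co-blocks.
#' @slot densityIn,densityOut within- and between-block association
#'   probabilities; `densityIn > densityOut` required.
#' @slot simIn,simOut within- and between-block similarity baselines;
#'   `simIn > simOut` required.
#' @slot noiseSd standard deviation of additive Gaussian similarity noise.
#' @slot seed integer seed for the generator's private RNG stream.
#' @export
setClass("SyntheticConfig", representation(
  nL = "integer", nD = "integer", nBlocks = "integer",
  densityIn = "numeric", densityOut = "numeric",
  simIn = "numeric", simOut = "numeric",
  noiseSd = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@nL < 1L || object@nD < 1L) return("nL and nD must be positive")
  if (object@nBlocks < 1L || object@nBlocks > min(object@nL, object@nD))
    return("nBlocks must be between 1 and min(nL, nD)")
  if (!(object@densityIn > 0 && object@densityIn <= 1))
    return("densityIn must be in (0, 1]")
  if (!(object@densityOut >= 0 && object@densityOut < 1))
    return("densityOut must be in [0, 1)")
  if (object@densityIn <= object@densityOut)
    return("densityIn must exceed densityOut")
  if (!(object@simIn > 0 && object@simIn <= 1)) return("simIn must be in (0, 1]")
  if (!(object@simOut >= 0 && object@simOut < 1)) return("simOut must be in [0, 1)")
  if (object@simIn <= object@simOut) return("simIn must exceed simOut")
  if (object@noiseSd < 0) return("noiseSd must be nonnegative")
  TRUE
})

#' @param nL,nD numbers of lncRNAs and diseases; defaults 60 and 40.
#' @param nBlocks number of co-blocks; default 4.
#' @param densityIn,densityOut association probabilities; defaults 0.25,
#'   0.01.
#' @param simIn,simOut similarity baselines; defaults 0.8, 0.1.
#' @param noiseSd similarity noise standard deviation; default 0.05.
#' @param seed integer RNG seed; default 1.
#' @rdname SyntheticConfig-class
#' @export
SyntheticConfig <- function(nL = 60L, nD = 40L, nBlocks = 4L,
                            densityIn = 0.25, densityOut = 0.01,
                            simIn = 0.8, simOut = 0.1,
                            noiseSd = 0.05, seed = 1L) {
  cfg <- try(new("SyntheticConfig", nL = as.integer(nL), nD = as.integer(nD),
      nBlocks = as.integer(nBlocks), densityIn = as.numeric(densityIn),
      densityOut = as.numeric(densityOut), simIn = as.numeric(simIn),
      simOut = as.numeric(simOut), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed)), silent = TRUE)
  if (inherits(cfg, "try-error"))
    lparpError("config", attr(cfg, "condition")$message)
  cfg
}
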