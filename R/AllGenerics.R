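#' Accessors for lparp objects
#'
#' `lncRNANames()` and `diseaseNames()` return the identifier index of each
#' node set; `simKind()` the construction tag of a similarity matrix;
#' `cvAUC()`, `rocPoints()` and `foldScores()` the components of a
#' cross-validation result.
#'
#' @param x an object of the documented class.
#' @return character vectors of identifiers, a kind tag, a numeric AUC, or
#'   data frames, respectively.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("lncRNANames", function(x) standardGeneric("lncRNANames"))

#' @rdname accessors
#' @export
setGeneric("diseaseNames", function(x) standardGeneric("diseaseNames"))

#' @rdname accessors
#' @export
setGeneric("simKind", function(x) standardGeneric("simKind"))

#' @rdname accessors
#' @export
setGeneric("cvAUC", function(x) standardGeneric("cvAUC"))

#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname accessors
#' @export
setGeneric("foldScores", function(x) standardGeneric("foldScores"))

#' @rdname accessors
#' @export
setMethod("lncRNANames", "AssociationMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("diseaseNames", "AssociationMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("lncRNANames", "ScoreMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("diseaseNames", "ScoreMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("simKind", "SimilarityMatrix", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("cvAUC", "CVResult", function(x) x@auc)

#' @rdname accessors
#' @export
setMethod("rocPoints", "CVResult", function(x) x@rocPoints)

#' @rdname accessors
#' @export
setMethod("foldScores", "CVResult", function(x) x@foldScores)

#' @rdname accessors
#' @export
setGeneric("dagNodes", function(x) standardGeneric("dagNodes"))

#' @rdname accessors
#' @export
setMethod("dagNodes", "DiseaseDAG", function(x) igraph::V(x@graph)$name)

#' @rdname accessors
#' @export
setGeneric("dagEdges", function(x) standardGeneric("dagEdges"))

#' @rdname accessors
#' @export
setMethod("dagEdges", "DiseaseDAG", function(x) {
  e <- igraph::as_edgelist(x@graph)
  data.frame(child = e[, 1L], parent = e[, 2L])
})

setMethod("show", "AssociationMatrix", function(object) {
  cat(sprintf("AssociationMatrix: %d lncRNAs x %d diseases, %d known associations (density %.2f%%)\n",
      nrow(object), ncol(object), sum(object@.Data),
      100 * mean(object@.Data)))
  invisible(NULL)
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s): %d x %d, mean off-diagonal %.4f\n",
      object@kind, nrow(object), ncol(object),
      if (nrow(object) > 1L)
        mean(object@.Data[row(object@.Data) != col(object@.Data)]) else NA_real_))
  invisible(NULL)
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix: %d x %d, score range [%.4g, %.4g]\n",
      nrow(object), ncol(object), min(object@.Data), max(object@.Data)))
  invisible(NULL)
})

setMethod("show", "DiseaseDAG", function(object) {
  cat(sprintf("DiseaseDAG: %d terms, %d child->parent edges\n",
      igraph::gorder(object@graph), igraph::gsize(object@graph)))
  invisible(NULL)
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult (%s): %d folds, %d pooled negatives, AUC = %.4f\n",
      object@protocol, nrow(object@foldScores), length(object@negScores),
      object@auc))
  invisible(NULL)
})

setMethod("show", "PropagationParams", function(object) {
  cat(sprintf("PropagationParams: alpha=%g beta=%g tol=%g maxIter=%d normalization=%s\n",
      object@alpha, object@beta, object@tol, object@maxIter,
      object@normalization))
  invisible(NULL)
})

setMethod("show", "GipParams", function(object) {
  cat(sprintf("GipParams: gammaPrime=%g\n", object@gammaPrime))
  invisible(NULL)
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d x %d, %d blocks, density %g/%g, sim %g/%g, noise %g, seed %d\n",
    object@nL, object@nD, object@nBlocks, object@densityIn, object@densityOut,
    object@simIn, object@simOut, object@noiseSd, object@seed))
  invisible(NULL)
})
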