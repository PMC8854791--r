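## Small in-code fixture builders shared across test files.

mkAssoc <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  dimnames(m) <- list(sprintf("L%d", seq_len(nrow(m))),
                      sprintf("D%d", seq_len(ncol(m))))
  AssociationMatrix(m)
}

mkSim <- function(m, kind = "integrated", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("N%d", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  SimilarityMatrix(m, kind = kind)
}

## Random symmetric nonnegative similarity with unit diagonal.
randSim <- function(n, kind = "integrated") {
  A <- matrix(runif(n * n), n, n)
  S <- (A + t(A)) / 2
  diag(S) <- 1
  mkSim(S, kind)
}

## Random sparse binary association matrix guaranteed nonempty on both
## margins in expectation; re-drawn until at least `minOnes` ones.
randAssoc <- function(nl, nd, p = 0.3, minOnes = 2L) {
  repeat {
    m <- matrix(as.numeric(runif(nl * nd) < p), nl, nd)
    if (sum(m) >= minOnes) return(mkAssoc(m))
  }
}

## Random DAG on `n` nodes: edges only point from later to earlier nodes
## in a fixed order, so acyclicity is guaranteed by construction.
randDagEdges <- function(n, pEdge = 0.5) {
  nodes <- LETTERS[seq_len(n)]
  from <- character(0); to <- character(0)
  for (i in seq(2L, n)) {
    parents <- which(runif(i - 1L) < pEdge)
    if (length(parents) == 0L) parents <- sample.int(i - 1L, 1L)
    from <- c(from, rep(nodes[i], length(parents)))
    to <- c(to, nodes[parents])
  }
  data.frame(child = from, parent = to)
}
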