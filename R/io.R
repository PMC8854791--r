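## File formats: TSV with header (CSV accepted for edge lists), UTF-8,
## row+column headers for matrices. Chosen for unambiguous round-tripping.

.readTable <- function(path) {
  if (!file.exists(path))
    lparpError("format", sprintf("file not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#",
                    quote = "")
}

#' Read an lncRNA-disease association edge list
#'
#' Materializes the binary incidence matrix `LD` from a long-format edge
#' list (TSV, or CSV by file extension) with one row per known
#' association. Duplicate rows collapse to a single 1. Row and column
#' indices are ordered by first appearance in the file and are stable for
#' the run; identifiers match exactly (case-sensitive), with no
#' disease-name normalization.
#'
#' @param path path to the edge-list file (header row required).
#' @param lncRNACol,diseaseCol names of the lncRNA and disease identifier
#'   columns; defaults `"lncRNA_id"` and `"disease_id"`.
#' @return an [AssociationMatrix-class] object.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("lncRNA_id\tdisease_id", "L1\tD1", "L1\tD2", "L2\tD2"), tf)
#' readAssociations(tf)
#' @export
readAssociations <- function(path, lncRNACol = "lncRNA_id",
                             diseaseCol = "disease_id") {
  df <- tryCatch(.readTable(path), error = function(e) {
    if (inherits(e, "lparp_error")) stop(e)
    lparpError("empty_input", sprintf("cannot read '%s': %s", path,
                                      conditionMessage(e)))
  })
  if (nrow(df) == 0L)
    lparpError("empty_input", sprintf("no data rows in '%s'", path))
  missing <- setdiff(c(lncRNACol, diseaseCol), names(df))
  if (length(missing))
    lparpError("format", sprintf("missing column(s): %s",
                                 paste(missing, collapse = ", ")))
  l <- as.character(df[[lncRNACol]])
  d <- as.character(df[[diseaseCol]])
  lids <- unique(l)
  dids <- unique(d)
  m <- matrix(0, length(lids), length(dids), dimnames = list(lids, dids))
  m[cbind(match(l, lids), match(d, dids))] <- 1
  AssociationMatrix(m)
}

#' Write an association matrix back to an edge list
#'
#' Inverse of [readAssociations()]: emits one `(lncRNA_id, disease_id)`
#' row per known association, in row-major order, so that reading the file
#' back reproduces the matrix exactly.
#'
#' @param LD an [AssociationMatrix-class] object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeAssociations <- function(LD, path) {
  stopifnot(is(LD, "AssociationMatrix"))
  idx <- which(t(LD@.Data) == 1, arr.ind = TRUE)  # row-major traversal
  df <- data.frame(lncRNA_id = rownames(LD)[idx[, 2L]],
                   disease_id = colnames(LD)[idx[, 1L]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled square similarity matrix
#'
#' Reads a TSV matrix with row and column headers, checks nonnegativity,
#' restricts and reorders it to `ids`, and enforces symmetry as
#' `(S + t(S)) / 2`. Asymmetry up to 1e-8 (numeric round-off in files) is
#' repaired silently; larger asymmetry is repaired with a warning.
#'
#' @param path path to the matrix TSV (first column = row labels).
#' @param ids character vector of node identifiers defining the target
#'   order; the file's labels must be a superset (or exact match).
#' @param kind construction tag for the result; default `"integrated"`.
#' @return a [SimilarityMatrix-class] object in `ids` order.
#' @export
readSimilarity <- function(path, ids, kind = "integrated") {
  if (!file.exists(path))
    lparpError("format", sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE, comment.char = "#")
  m <- as.matrix(df)
  if (!is.numeric(m))
    lparpError("format", sprintf("non-numeric entries in '%s'", path))
  if (nrow(m) != ncol(m))
    lparpError("format", sprintf("matrix in '%s' is not square", path))
  if (!setequal(rownames(m), colnames(m)))
    lparpError("index", "row and column labels disagree")
  ids <- as.character(ids)
  absent <- setdiff(ids, rownames(m))
  if (length(absent))
    lparpError("index", sprintf("similarity file lacks %d id(s), e.g. '%s'",
                                length(absent), absent[1L]))
  m <- m[ids, ids, drop = FALSE]
  if (any(m < 0))
    lparpError("domain", "negative similarity entries")
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8)
    warning(sprintf("symmetrizing similarity matrix (max asymmetry %.3g)",
                    asym))
  m <- (m + t(m)) / 2
  SimilarityMatrix(m, kind = kind)
}

#' Write a similarity or score matrix as labeled TSV
#' @param x a matrix-like object with dimnames.
#' @param path output TSV path.
#' @param header optional character vector written as leading `#` comment
#'   lines.
#' @return `path`, invisibly.
#' @export
writeMatrixTSV <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  m <- as.matrix(x)
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a disease term DAG from a child/parent edge list
#'
#' Expects a two-column TSV with header columns `child` and `parent`,
#' one edge per row, directed child -> parent. A cycle check is performed.
#'
#' @param path path to the edge TSV.
#' @return a [DiseaseDAG-class] object.
#' @export
readDiseaseDAG <- function(path) {
  df <- .readTable(path)
  missing <- setdiff(c("child", "parent"), names(df))
  if (length(missing))
    lparpError("format", sprintf("missing column(s): %s",
                                 paste(missing, collapse = ", ")))
  DiseaseDAG(df[, c("child", "parent")])
}

## Competition ("1,1,3") rank of each value among `v`, larger is better.
.competitionRank <- function(v) {
  vapply(v, function(s) 1L + sum(v > s), integer(1L))
}

#' Write ranked candidate scores as long-format TSV
#'
#' Emits one row per (lncRNA, disease) pair with the prediction score and
#' the competition rank of the pair within its disease column (ties share
#' the best rank: "1,1,3"). When the training association matrix is given,
#' known pairs are flagged so that candidate lists can exclude them. With
#' `topK`, only the `topK` best-ranked rows per disease are written (ties
#' broken by lncRNA index order, so at most `topK` rows per disease).
#'
#' @param scores a [ScoreMatrix-class] (lncRNA x disease).
#' @param path output TSV path.
#' @param topK positive integer, or `NULL` (default) for all rows.
#' @param known optional [AssociationMatrix-class] of training pairs.
#' @param header optional character vector of `#` comment lines (used by
#'   the CLI to stamp the effective configuration).
#' @return `path`, invisibly.
#' @export
writeScores <- function(scores, path, topK = NULL, known = NULL,
                        header = NULL) {
  stopifnot(is(scores, "ScoreMatrix"))
  m <- scores@.Data
  if (!all(is.finite(m)))
    lparpError("domain", "non-finite scores cannot be written")
  if (!is.null(known)) {
    stopifnot(is(known, "AssociationMatrix"))
    if (!identical(dim(known), dim(m)))
      lparpError("dimension", "known-association matrix shape mismatch")
  }
  parts <- lapply(seq_len(ncol(m)), function(j) {
    s <- m[, j]
    r <- .competitionRank(s)
    ord <- order(r, seq_along(s))
    if (!is.null(topK)) ord <- utils::head(ord, topK)
    out <- data.frame(lncRNA_id = rownames(m)[ord],
                      disease_id = colnames(m)[j],
                      score = s[ord],
                      rank_within_disease = r[ord])
    if (!is.null(known)) out$known = known@.Data[ord, j] == 1
    out
  })
  df <- do.call(rbind, parts)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
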