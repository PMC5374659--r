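#' Construct a sparse node-similarity table
#'
#' Holds pairwise similarity scores s(query node, target node), typically
#' BLAST bit scores. Only strictly positive entries are stored; looking up
#' an absent pair returns 0. Duplicate pairs keep the maximum score.
#'
#' @param query_ids,target_ids,scores parallel vectors describing the
#'   positive entries
#' @return an object of class `similarity_table`
#' @export
similarity_table <- function(query_ids = character(), target_ids = character(),
                             scores = numeric()) {
  query_ids <- as.character(query_ids)
  target_ids <- as.character(target_ids)
  scores <- as.numeric(scores)
  stopifnot(length(query_ids) == length(target_ids),
            length(query_ids) == length(scores))
  keep <- is.finite(scores) & scores > 0
  if (any(!keep)) {
    warning(sum(!keep), " non-positive similarity score(s) skipped")
    query_ids <- query_ids[keep]; target_ids <- target_ids[keep]
    scores <- scores[keep]
  }
  key <- paste(query_ids, target_ids, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate similarity pair(s): keeping maximum score")
    mx <- tapply(scores, key, max)
    parts <- strsplit(names(mx), "\r", fixed = TRUE)
    query_ids <- vapply(parts, `[`, "", 1L)
    target_ids <- vapply(parts, `[`, "", 2L)
    scores <- as.numeric(mx)
  }
  qlev <- sort(unique(query_ids)); tlev <- sort(unique(target_ids))
  mat <- Matrix::sparseMatrix(
    i = match(query_ids, qlev), j = match(target_ids, tlev), x = scores,
    dims = c(length(qlev), length(tlev)), dimnames = list(qlev, tlev)
  )
  structure(list(mat = mat), class = "similarity_table")
}

#' @export
print.similarity_table <- function(x, ...) {
  cat("similarity_table:", nrow(x$mat), "query x", ncol(x$mat),
      "target nodes,", length(x$mat@x), "positive entries\n")
  invisible(x)
}

#' Look up similarity scores
#'
#' @param sim a [similarity_table]
#' @param query_ids,target_ids parallel id vectors
#' @return numeric vector of scores; 0 for absent pairs or unknown ids
#' @export
sim_score <- function(sim, query_ids, target_ids) {
  qi <- match(as.character(query_ids), rownames(sim$mat))
  ti <- match(as.character(target_ids), colnames(sim$mat))
  out <- numeric(length(qi))
  ok <- !is.na(qi) & !is.na(ti)
  if (any(ok)) out[ok] <- sim$mat[cbind(qi[ok], ti[ok])]
  out
}

#' Submatrix of similarity scores for given node sets
#'
#' @param sim a [similarity_table]
#' @param query_nodes,target_nodes node id vectors; ids absent from the
#'   table get all-zero rows/columns
#' @return a sparse dgCMatrix with `query_nodes` rows, `target_nodes` cols
#' @export
sim_matrix <- function(sim, query_nodes, target_nodes) {
  query_nodes <- as.character(query_nodes)
  target_nodes <- as.character(target_nodes)
  out <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(length(query_nodes), length(target_nodes)),
                              dimnames = list(query_nodes, target_nodes))
  qi <- match(query_nodes, rownames(sim$mat))
  ti <- match(target_nodes, colnames(sim$mat))
  qok <- which(!is.na(qi)); tok <- which(!is.na(ti))
  if (length(qok) && length(tok)) {
    sub <- sim$mat[qi[qok], ti[tok], drop = FALSE]
    out[qok, tok] <- sub
  }
  methods::as(out, "CsparseMatrix")
}

#' All stored (positive) similarity scores
#' @param sim a [similarity_table]
#' @return numeric vector
#' @export
sim_positive_scores <- function(sim) sim$mat@x
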