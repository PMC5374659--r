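# Target-network pre-processing: homology filtering and pseudo-edge
# re-connection. Both steps operate on copies; inputs are never modified.

#' Remove non-homologous nodes from the target network
#'
#' Keeps every target node whose similarity to at least one query node
#' strictly exceeds `threshold` (with the default threshold 0 this keeps
#' nodes that have any positive similarity to the query) and returns the
#' induced subgraph. Shrinking the target this way cuts the state space of
#' the random walk dramatically, since real PPI targets are far larger
#' than the query module.
#'
#' @param target target network (igraph)
#' @param sim a [similarity_table]
#' @param query query network (igraph); only similarities to its nodes count
#' @param threshold similarity threshold `T_h` (>= 0, default 0; strict >)
#' @return induced subnetwork of `target` (possibly empty)
#' @export
reduce_target <- function(target, sim, query, threshold = 0) {
  stopifnot(threshold >= 0)
  tn <- net_nodes(target)
  sm <- sim_matrix(sim, net_nodes(query), tn)
  best <- apply_colmax_sparse(sm)
  induced_network(target, tn[best > threshold])
}

# column maxima of a sparse nonneg matrix, 0 for empty columns
apply_colmax_sparse <- function(m) {
  m <- methods::as(m, "CsparseMatrix")
  out <- numeric(ncol(m))
  dp <- diff(m@p)
  if (length(m@x)) {
    col <- rep.int(seq_len(ncol(m)), dp)
    mx <- tapply(m@x, col, max)
    out[as.integer(names(mx))] <- as.numeric(mx)
  }
  out
}

#' Re-connect a reduced target network with pseudo-edges
#'
#' Homology filtering can disconnect the target network. For every pair of
#' target nodes lying in *different* connected components of the input
#' graph, a pseudo-edge (weight 1, `is_pseudo = TRUE`) is added when some
#' query node has high similarity to both — the rationale being that two
#' proteins resembling the same query protein are likely to share
#' function and may interact. "High" means at or above the
#' `sim_quantile` quantile of all stored positive scores; the default
#' quantile 0 accepts any positive score. Component membership is
#' evaluated once on the input graph, so insertion is a single batch and
#' does not cascade.
#'
#' @param reduced reduced target network (>= 1 node)
#' @param sim a [similarity_table]
#' @param sim_quantile quantile in `[0, 1)` defining "high" similarity
#' @return `reduced` plus pseudo-edges; never modifies existing edges
#' @export
insert_pseudo_edges <- function(reduced, sim, sim_quantile = 0) {
  stopifnot(igraph::vcount(reduced) >= 1L,
            sim_quantile >= 0, sim_quantile < 1)
  pos <- sim_positive_scores(sim)
  if (!length(pos)) return(reduced)
  thr <- if (sim_quantile == 0) 0 else
    as.numeric(stats::quantile(pos, sim_quantile, names = FALSE))
  comp <- igraph::components(reduced)$membership
  tn <- net_nodes(reduced)
  # for each query node: target nodes of `reduced` it scores highly against
  sm <- sim_matrix(sim, rownames(sim$mat), tn)
  new_a <- character(); new_b <- character()
  for (qi in seq_len(nrow(sm))) {
    row <- sm[qi, ]
    hits <- which(if (thr == 0) row > 0 else row >= thr)
    if (length(hits) < 2L) next
    prs <- utils::combn(hits, 2L)
    diff_comp <- comp[prs[1L, ]] != comp[prs[2L, ]]
    if (any(diff_comp)) {
      new_a <- c(new_a, tn[prs[1L, diff_comp]])
      new_b <- c(new_b, tn[prs[2L, diff_comp]])
    }
  }
  if (!length(new_a)) return(reduced)
  a <- pmin(new_a, new_b); b <- pmax(new_a, new_b)
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  out <- igraph::add_edges(reduced,
                           rbind(a[keep], b[keep]),
                           weight = 1, is_pseudo = TRUE)
  out
}
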