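#' Construct an undirected interaction network
#'
#' Networks are stored as undirected [igraph][igraph::igraph-package]
#' graphs with a character `name` vertex attribute and `weight` /
#' `is_pseudo` edge attributes. Node identifiers are opaque,
#' case-sensitive strings. Self-loops are disallowed and duplicate edges
#' collapse to a single edge keeping the maximum weight (a conservative
#' merge of redundant interaction records).
#'
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `weight` (positive; default 1) and `is_pseudo` (logical, default
#'   `FALSE`).
#' @param nodes optional character vector of node ids; ids appearing in
#'   `edges` are always included.
#' @return an igraph object
#' @export
make_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    if (!is.null(nodes)) g <- igraph::add_vertices(g, length(nodes), name = as.character(nodes))
    return(g)
  }
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  w <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, length(from))
  ps <- if ("is_pseudo" %in% names(edges)) as.logical(edges$is_pseudo) else rep(FALSE, length(from))
  if (any(!is.finite(w)) || any(w <= 0)) stop("all edge weights must be positive and finite")
  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    from <- from[!loops]; to <- to[!loops]; w <- w[!loops]; ps <- ps[!loops]
  }
  # canonical unordered pairs; duplicates keep max weight (pseudo if all dups pseudo)
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    w <- tapply(w, key, max)
    ps <- tapply(ps, key, all)
    a <- vapply(strsplit(names(w), "\r", fixed = TRUE), `[`, "", 1L)
    b <- vapply(strsplit(names(w), "\r", fixed = TRUE), `[`, "", 2L)
    w <- as.numeric(w); ps <- as.logical(ps)
  }
  all_nodes <- union(union(a, b), as.character(nodes %||% character()))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, weight = w, is_pseudo = ps,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE)
  )
  g
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Node identifiers of a network
#' @param net an igraph network
#' @return character vector of node ids
#' @export
net_nodes <- function(net) igraph::V(net)$name

#' Canonical edge table of a network
#'
#' Edges are returned with endpoints ordered lexicographically within each
#' row and rows sorted, so two networks with the same edge set yield
#' identical tables.
#'
#' @param net an igraph network
#' @return data.frame with columns `from`, `to`, `weight`, `is_pseudo`
#' @export
net_edges <- function(net) {
  if (igraph::ecount(net) == 0L) {
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), is_pseudo = logical(),
                      stringsAsFactors = FALSE))
  }
  el <- igraph::as_edgelist(net, names = TRUE)
  w <- igraph::E(net)$weight %||% rep(1, nrow(el))
  ps <- igraph::E(net)$is_pseudo %||% rep(FALSE, nrow(el))
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  o <- order(a, b)
  data.frame(from = a[o], to = b[o], weight = w[o], is_pseudo = ps[o],
             stringsAsFactors = FALSE)
}

#' Induced subgraph on a node subset
#' @param net an igraph network
#' @param members character vector of node ids (must exist in `net`)
#' @return igraph network on `members` with the induced edges
#' @export
induced_network <- function(net, members) {
  stopifnot(all(members %in% net_nodes(net)))
  igraph::induced_subgraph(net, members)
}
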