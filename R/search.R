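# Seed-network construction, conductance, greedy extension, pruning, and
# the full querying pipeline.

#' A node subset of a parent network
#'
#' Lightweight handle pairing a parent network with a member node set;
#' induced edges are always derived from the parent, never stored.
#'
#' @param parent igraph network
#' @param members character vector of member node ids (subset of parent)
#' @return object of class `subnetwork`
#' @export
subnetwork <- function(parent, members) {
  members <- sort(unique(as.character(members)))
  if (!all(members %in% net_nodes(parent))) {
    stop("subnetwork members must belong to the parent network")
  }
  structure(list(parent = parent, members = members), class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("subnetwork:", length(x$members), "of", igraph::vcount(x$parent),
      "nodes\n")
  invisible(x)
}

#' Build the seed network from selected seed nodes
#'
#' Takes the subgraph of the target induced on the seed nodes and keeps
#' its largest connected component. Component-size ties go to the
#' component containing the best-ranked seed, then to the component with
#' the lexicographically smallest member. If the induced subgraph has no
#' edges at all, the single best-ranked seed is returned.
#'
#' @param target target network (igraph)
#' @param seeds a `seed_list` from [select_seeds()] (ranked best first)
#' @return a [subnetwork] of `target`
#' @export
seed_network <- function(target, seeds) {
  if (is.data.frame(seeds)) {
    snodes <- seeds$node
  } else {
    snodes <- as.character(seeds)
  }
  if (!length(snodes)) stop("empty seed list")
  sub <- induced_network(target, snodes)
  if (igraph::ecount(sub) == 0L) return(subnetwork(target, snodes[1L]))
  comp <- igraph::components(sub)
  rank_of <- stats::setNames(seq_along(snodes), snodes)
  best <- NULL; best_key <- NULL
  for (ci in seq_len(comp$no)) {
    mem <- net_nodes(sub)[comp$membership == ci]
    key <- list(-length(mem), min(rank_of[mem]), min(mem))
    if (is.null(best) ||
        key[[1]] < best_key[[1]] ||
        (key[[1]] == best_key[[1]] && key[[2]] < best_key[[2]]) ||
        (key[[1]] == best_key[[1]] && key[[2]] == best_key[[2]] &&
         key[[3]] < best_key[[3]])) {
      best <- mem; best_key <- key
    }
  }
  subnetwork(target, best)
}

#' Network conductance of a subnetwork
#'
#' With `cut` the number of edges having exactly one endpoint in the
#' subnetwork `H` and `internal` the number of edges with both endpoints
#' inside, the two definitions are:
#'
#' * `mode = "module"` (default): `cut / internal`, the working
#'   definition during extension — valid when the module is much smaller
#'   than the rest of the target, so its volume is dominated by internal
#'   edges. Returns `Inf` when `internal == 0`.
#' * `mode = "standard"`: `cut / min(vol(H), vol(complement))` with
#'   `vol` the sum of node degrees; the textbook definition, bounded in
#'   `[0, 1]` whenever both sides have positive volume.
#'
#' Edges are counted unweighted in both modes; weights only influence the
#' random walk.
#'
#' @param parent igraph network
#' @param H a [subnetwork] of `parent`, or a character vector of node ids
#' @param mode `"module"` or `"standard"`
#' @return nonnegative real (possibly `Inf`)
#' @export
conductance <- function(parent, H, mode = c("module", "standard")) {
  mode <- match.arg(mode)
  members <- if (inherits(H, "subnetwork")) H$members else as.character(H)
  if (!length(members)) stop("subnetwork must be non-empty")
  if (!all(members %in% net_nodes(parent))) {
    stop("subnetwork members must belong to the parent network")
  }
  el <- igraph::as_edgelist(parent, names = TRUE)
  ina <- el[, 1] %in% members
  inb <- el[, 2] %in% members
  cut <- sum(xor(ina, inb))
  internal <- sum(ina & inb)
  if (mode == "module") {
    if (internal == 0L) return(Inf)
    return(cut / internal)
  }
  vol_h <- 2 * internal + cut
  vol_rest <- 2 * (nrow(el) - internal - cut) + cut
  denom <- min(vol_h, vol_rest)
  if (denom == 0L) return(if (cut == 0L) 0 else Inf)
  cut / denom
}

#' Greedily extend a seed network by minimizing conductance
#'
#' Repeatedly scans all nodes adjacent to the current subnetwork and adds
#' the one yielding the lowest conductance of the enlarged subnetwork,
#' provided it reduces the current conductance by at least the `reduction`
#' fraction (any finite conductance is an acceptable improvement over
#' `Inf`). Extension stops when no candidate qualifies or when the
#' subnetwork would exceed `cap_factor` times the query size. When a node
#' `u` is accepted, every existing member adjacent to `u` earns an
#' extension reward of +1 (`u` itself starts at 0); rewards thus measure
#' each node's contribution to densifying the module and later drive
#' pruning. Candidate ties are broken by lower seed-selection log-score
#' (more seed-like first), then lexicographic node id.
#'
#' @param parent target network (igraph)
#' @param seedH starting [subnetwork]
#' @param query_size number of nodes of the query network
#' @param scores named log-score vector from [seed_scores()] used for tie
#'   breaking; nodes missing from it rank last
#' @param reduction minimum relative conductance reduction in `(0, 1)`
#' @param cap_factor size cap as a multiple of `query_size` (>= 1)
#' @return list with elements `subnetwork`, `rewards` (named integer
#'   vector over the final members), `trace` (conductance after each
#'   step, starting value first), `steps` (data.frame of accepted nodes
#'   and their conductance)
#' @export
extend <- function(parent, seedH, query_size, scores = numeric(),
                   reduction = 0.05, cap_factor = 2) {
  stopifnot(inherits(seedH, "subnetwork"),
            reduction > 0, reduction < 1, cap_factor >= 1)
  nodes <- net_nodes(parent)
  deg <- igraph::degree(parent)
  adj <- igraph::as_adj_list(parent)          # list of igraph.vs
  adj <- lapply(adj, function(v) nodes[as.integer(v)])
  names(adj) <- nodes
  inH <- stats::setNames(nodes %in% seedH$members, nodes)

  internal <- sum(vapply(seedH$members, function(u) sum(inH[adj[[u]]]), 0)) / 2
  cut <- sum(deg[seedH$members]) - 2 * internal
  phi <- if (internal == 0) Inf else cut / internal

  rewards <- stats::setNames(integer(length(seedH$members)), seedH$members)
  trace <- phi
  acc_nodes <- character(); acc_phi <- numeric()
  cap <- floor(cap_factor * query_size)
  tie_score <- function(u) if (u %in% names(scores)) scores[[u]] else Inf

  repeat {
    members <- names(rewards)
    if (length(members) + 1L > cap) break
    cand <- setdiff(unique(unlist(adj[members], use.names = FALSE)), members)
    if (!length(cand)) break
    k_in <- vapply(cand, function(u) sum(inH[adj[[u]]]), 0)
    internal_new <- internal + k_in
    cut_new <- cut + deg[cand] - 2 * k_in
    phi_new <- ifelse(internal_new == 0, Inf, cut_new / internal_new)
    acceptable <- if (is.infinite(phi)) is.finite(phi_new) else
      phi_new <= (1 - reduction) * phi
    if (!any(acceptable)) break
    cand <- cand[acceptable]; phi_new <- phi_new[acceptable]
    k_in <- k_in[acceptable]
    ts <- vapply(cand, tie_score, 0)
    o <- order(phi_new, ts, cand)
    u <- cand[o[1L]]
    phi <- unname(phi_new[o[1L]])
    internal <- internal + k_in[o[1L]]
    cut <- cut + deg[[u]] - 2 * k_in[o[1L]]
    nb_in <- adj[[u]][inH[adj[[u]]]]
    rewards[nb_in] <- rewards[nb_in] + 1L
    rewards[u] <- 0L
    inH[u] <- TRUE
    trace <- c(trace, phi)
    acc_nodes <- c(acc_nodes, u); acc_phi <- c(acc_phi, phi)
  }

  list(subnetwork = subnetwork(parent, names(rewards)),
       rewards = rewards,
       trace = trace,
       steps = data.frame(node = acc_nodes, conductance = acc_phi,
                          stringsAsFactors = FALSE))
}

#' Prune an extended subnetwork by extension reward
#'
#' Retains a node iff it is a seed or its extension reward strictly
#' exceeds `threshold`; loosely attached extension nodes (few links to
#' later additions) are removed to sharpen functional coherence. The
#' result may be disconnected; connectivity is reported, not enforced.
#'
#' @param H a [subnetwork]
#' @param rewards named integer vector of extension rewards
#' @param seeds character vector of protected seed node ids
#' @param threshold nonnegative integer (default 0)
#' @return pruned [subnetwork]
#' @export
prune <- function(H, rewards, seeds, threshold = 0L) {
  stopifnot(inherits(H, "subnetwork"), threshold >= 0)
  keep <- H$members %in% seeds |
    (H$members %in% names(rewards) & rewards[H$members] > threshold)
  subnetwork(H$parent, H$members[keep])
}

#' Run the full network-querying pipeline
#'
#' Composes the stages in order: reduce the target to nodes with query
#' homologs, re-connect with pseudo-edges, estimate node correspondence
#' with the context-sensitive random walk, normalize, select seed nodes,
#' build the seed network, extend it greedily by conductance
#' minimization, and prune by extension reward. All stages are
#' deterministic, so identical inputs give identical results.
#'
#' @param query query network (igraph)
#' @param target target network (igraph)
#' @param sim a [similarity_table]
#' @param config configuration list, see [default_config()]
#' @param query_id identifier recorded in the result
#' @return a [query_result] object
#' @export
run_query <- function(query, target, sim, config = default_config(),
                      query_id = "query") {
  reduced <- reduce_target(target, sim, query,
                           threshold = config[["preprocess.threshold"]])
  if (igraph::vcount(reduced) == 0L) {
    stop("reduced target network is empty: no target node passes the ",
         "similarity threshold")
  }
  if (isTRUE(config[["preprocess.enable_pseudo_edges"]])) {
    reduced <- insert_pseudo_edges(reduced, sim,
                                   config[["preprocess.pseudo_sim_quantile"]])
  }
  C <- correspondence(query, reduced, sim, config)
  Cbar <- normalize_correspondence(C)
  n_q <- config[["seeds.n_q"]]
  if (is.na(n_q)) n_q <- igraph::vcount(query)
  seeds <- select_seeds(Cbar, n_q = n_q)
  seedH <- seed_network(reduced, seeds)
  ext <- extend(reduced, seedH,
                query_size = igraph::vcount(query),
                scores = seed_scores(Cbar),
                reduction = config[["extend.reduction"]],
                cap_factor = config[["extend.cap_factor"]])
  final <- prune(ext$subnetwork, ext$rewards, seedH$members,
                 threshold = config[["prune.threshold"]])
  provenance <- stats::setNames(
    ifelse(ext$subnetwork$members %in% seedH$members, "seed",
           ifelse(ext$subnetwork$members %in% final$members,
                  "extended", "pruned")),
    ext$subnetwork$members)
  ncomp <- if (length(final$members)) {
    igraph::components(induced_network(reduced, final$members))$no
  } else 0L
  query_result(query_id = query_id,
               final = final$members,
               seeds = seedH$members,
               rewards = ext$rewards,
               trace = ext$trace,
               provenance = provenance,
               n_components = ncomp)
}
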