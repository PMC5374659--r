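# Independent brute-force oracles used across the suite. These are naive
# reimplementations (dense loops, exhaustive enumeration) that share no
# code with the package internals.

# random connected undirected graph as an edge data.frame
rand_connected_edges <- function(n, p, prefix = "n") {
  repeat {
    adj <- matrix(runif(n * n) < p, n, n)
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    el <- which(adj, arr.ind = TRUE)
    if (nrow(el) == 0L) next
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (igraph::vcount(g) == n && igraph::is_connected(g)) {
      ids <- sprintf("%s%02d", prefix, seq_len(n))
      return(data.frame(from = ids[el[, 1]], to = ids[el[, 2]],
                        weight = round(runif(nrow(el), 0.5, 2), 3),
                        stringsAsFactors = FALSE))
    }
  }
}

# random similarity table with npos distinct positive pairs
rand_sim <- function(query, target, npos) {
  qn <- net_nodes(query); tn <- net_nodes(target)
  npos <- min(npos, length(qn) * length(tn))
  pick <- sample(length(qn) * length(tn), npos)
  similarity_table(qn[(pick - 1L) %% length(qn) + 1L],
                   tn[(pick - 1L) %/% length(qn) + 1L],
                   runif(npos, 1, 100))
}

# Dense construction of the full CSRW joint transition operator over the
# complete pair space, by literal application of the walk rules.
# Returns list(P_sim, P_ind, pairs) with pairs a (q, t) index matrix.
dense_csrw_operator <- function(query, target, sim) {
  qn <- net_nodes(query); tn <- net_nodes(target)
  nq <- length(qn); nt <- length(tn)
  ns <- nq * nt
  S <- matrix(0, nq, nt, dimnames = list(qn, tn))
  for (q in qn) for (t in tn) S[q, t] <- sim_score(sim, q, t)
  wmat <- function(net) {
    ids <- net_nodes(net)
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    ed <- net_edges(net)
    for (i in seq_len(nrow(ed))) {
      m[ed$from[i], ed$to[i]] <- ed$weight[i]
      m[ed$to[i], ed$from[i]] <- ed$weight[i]
    }
    m
  }
  WQ <- wmat(query); WT <- wmat(target)
  idx <- function(qi, ti) (ti - 1L) * nq + qi
  P_sim <- matrix(0, ns, ns); P_ind <- matrix(0, ns, ns)
  for (qi in seq_len(nq)) for (ti in seq_len(nt)) {
    st <- idx(qi, ti)
    nbq <- which(WQ[qi, ] > 0); nbt <- which(WT[ti, ] > 0)
    simw <- matrix(0, length(nbq), length(nbt))
    if (length(nbq) && length(nbt)) {
      for (a in seq_along(nbq)) for (b in seq_along(nbt)) {
        simw[a, b] <- WQ[qi, nbq[a]] * WT[ti, nbt[b]] * S[nbq[a], nbt[b]]
      }
    }
    if (sum(simw) > 0) {
      simw <- simw / sum(simw)
      for (a in seq_along(nbq)) for (b in seq_along(nbt)) {
        P_sim[st, idx(nbq[a], nbt[b])] <-
          P_sim[st, idx(nbq[a], nbt[b])] + simw[a, b]
      }
    } else {
      if (length(nbq)) {
        for (a in seq_along(nbq)) {
          P_ind[st, idx(nbq[a], ti)] <- P_ind[st, idx(nbq[a], ti)] +
            0.5 * WQ[qi, nbq[a]] / sum(WQ[qi, ])
        }
      } else P_ind[st, st] <- P_ind[st, st] + 0.5
      if (length(nbt)) {
        for (b in seq_along(nbt)) {
          P_ind[st, idx(qi, nbt[b])] <- P_ind[st, idx(qi, nbt[b])] +
            0.5 * WT[ti, nbt[b]] / sum(WT[ti, ])
        }
      } else P_ind[st, st] <- P_ind[st, st] + 0.5
    }
  }
  list(P_sim = P_sim, P_ind = P_ind,
       pairs = cbind(q = rep(seq_len(nq), nt), t = rep(seq_len(nt), each = nq)),
       query_nodes = qn, target_nodes = tn)
}

# stationary distribution of a dense row-stochastic matrix by eigen-solve
dense_stationary <- function(P) {
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v / sum(v)
}

# oracle correspondence matrix: eigen stationary x simultaneous arrivals
oracle_correspondence <- function(query, target, sim) {
  op <- dense_csrw_operator(query, target, sim)
  P <- op$P_sim + op$P_ind
  pi_ <- dense_stationary(P)
  cvec <- as.numeric(pi_ %*% op$P_sim)
  C <- matrix(0, length(op$query_nodes), length(op$target_nodes),
              dimnames = list(op$query_nodes, op$target_nodes))
  C[op$pairs] <- cvec
  C
}

# is the full joint chain irreducible (single strongly connected class)?
joint_chain_irreducible <- function(query, target, sim) {
  op <- dense_csrw_operator(query, target, sim)
  P <- op$P_sim + op$P_ind
  g <- igraph::graph_from_adjacency_matrix(P > 0, mode = "directed")
  igraph::components(g, mode = "strong")$no == 1L
}

# brute-force conductance by scanning every edge
oracle_conductance <- function(net, members, mode = "module") {
  ed <- net_edges(net)
  cut <- 0L; internal <- 0L
  for (i in seq_len(nrow(ed))) {
    a_in <- ed$from[i] %in% members
    b_in <- ed$to[i] %in% members
    if (a_in && b_in) internal <- internal + 1L
    else if (a_in || b_in) cut <- cut + 1L
  }
  if (mode == "module") {
    if (internal == 0L) return(Inf)
    return(cut / internal)
  }
  deg <- igraph::degree(net)
  vol_h <- sum(deg[intersect(net_nodes(net), members)])
  vol_rest <- sum(deg[setdiff(net_nodes(net), members)])
  denom <- min(vol_h, vol_rest)
  if (denom == 0) return(if (cut == 0L) 0 else Inf)
  cut / denom
}

# exact hypergeometric upper tail by explicit enumeration of all draws
oracle_hypergeom_enum <- function(N, K, n, k) {
  universe <- seq_len(N)
  hits <- seq_len(K)
  draws <- utils::combn(universe, n)
  tail_count <- 0L
  for (j in seq_len(ncol(draws))) {
    if (sum(draws[, j] %in% hits) >= k) tail_count <- tail_count + 1L
  }
  tail_count / ncol(draws)
}
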