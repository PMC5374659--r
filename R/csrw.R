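# Context-sensitive random walk (CSRW) over query-target node pairs.
#
# The walker occupies a pair (v_q, v_t). Let
#   S = { (x, y) : x ~ v_q, y ~ v_t, s(x, y) > 0 }.
# If S is non-empty the walker moves *simultaneously* on both networks,
# to (x, y) with probability proportional to w(v_q,x) * w(v_t,y) * s(x,y),
# so that moves follow strong interactions toward similar node pairs. If
# S is empty (the context offers no jointly similar neighbors, e.g. near
# an inserted or deleted node) the walker picks one network uniformly and
# moves *individually* on it, to a neighbor chosen proportionally to edge
# weight, leaving the other coordinate fixed; a coordinate without
# neighbors stays in place on that half-step. The long-run rate at which
# the walker arrives at a pair by a simultaneous move is its node
# correspondence score c(v_q, v_t).
#
# The chain is iterated as a distribution (no sampling), with a lazy
# update p <- a*p + (1-a)*p%*%P that guarantees aperiodicity without
# changing the stationary distribution.

#' Build the CSRW transition operator
#'
#' Enumerates the pair states reachable from the initial support (all
#' pairs with positive similarity) and assembles two sparse blocks of the
#' transition operator: `P_sim` (simultaneous moves) and `P_ind`
#' (individual moves). Each row of `P_sim + P_ind` sums to 1; a row is
#' entirely simultaneous when the state has jointly similar neighbor
#' pairs and entirely individual otherwise.
#'
#' @param query,target non-empty igraph networks
#' @param sim a [similarity_table]; must have at least one positive entry
#'   between the two node sets
#' @return an object of class `csrw_chain` with elements `states`
#'   (two-column matrix of query/target node indices), `P_sim`, `P_ind`,
#'   `support` (state indices with s > 0), `query_nodes`, `target_nodes`
#' @export
build_chain <- function(query, target, sim) {
  qn <- net_nodes(query); tn <- net_nodes(target)
  if (!length(qn) || !length(tn)) stop("both networks must be non-empty")
  nq <- length(qn); nt <- length(tn)
  S <- sim_matrix(sim, qn, tn)            # nq x nt sparse
  Ssum <- methods::as(S, "TsparseMatrix")
  if (!length(Ssum@x)) {
    stop("walk has empty support: no positive similarity between query and target nodes")
  }

  # adjacency lists with weights
  adjq <- adj_list(query); adjt <- adj_list(target)

  support_keys <- (Ssum@j) * nq + (Ssum@i + 1L)  # key = qi + (ti-1)*nq
  key_of <- function(qi, ti) (ti - 1L) * nq + qi

  state_key <- integer(0)                  # discovery-ordered keys
  key2state <- integer(nq * nt)            # 0 = undiscovered
  push <- function(keys) {
    new <- keys[key2state[keys] == 0L]
    if (length(new)) {
      new <- unique(new)
      idx <- length(state_key) + seq_along(new)
      key2state[new] <<- idx
      state_key <<- c(state_key, new)
    }
  }
  push(sort(support_keys))

  si <- integer(0); sj <- integer(0); sx <- numeric(0)   # simultaneous triplets
  ii <- integer(0); ij <- integer(0); ix <- numeric(0)   # individual triplets
  done <- 0L
  while (done < length(state_key)) {
    st <- done + 1L
    done <- st
    key <- state_key[st]
    qi <- ((key - 1L) %% nq) + 1L
    ti <- ((key - 1L) %/% nq) + 1L
    nbq <- adjq[[qi]]; nbt <- adjt[[ti]]
    simblock <- NULL
    if (length(nbq$idx) && length(nbt$idx)) {
      ssub <- S[nbq$idx, nbt$idx, drop = FALSE]
      ssub <- methods::as(ssub, "TsparseMatrix")
      if (length(ssub@x)) {
        x <- nbq$idx[ssub@i + 1L]; y <- nbt$idx[ssub@j + 1L]
        wt <- nbq$w[ssub@i + 1L] * nbt$w[ssub@j + 1L] * ssub@x
        simblock <- list(keys = key_of(x, y), p = wt / sum(wt))
      }
    }
    if (!is.null(simblock)) {
      push(simblock$keys)
      si <- c(si, rep.int(st, length(simblock$keys)))
      sj <- c(sj, key2state[simblock$keys])
      sx <- c(sx, simblock$p)
    } else {
      # individual walk: one network w.p. 1/2 each; dangling side stays
      keys <- integer(0); p <- numeric(0)
      if (length(nbq$idx)) {
        keys <- c(keys, key_of(nbq$idx, rep.int(ti, length(nbq$idx))))
        p <- c(p, 0.5 * nbq$w / sum(nbq$w))
      } else { keys <- c(keys, key); p <- c(p, 0.5) }
      if (length(nbt$idx)) {
        keys <- c(keys, key_of(rep.int(qi, length(nbt$idx)), nbt$idx))
        p <- c(p, 0.5 * nbt$w / sum(nbt$w))
      } else { keys <- c(keys, key); p <- c(p, 0.5) }
      push(keys)
      ii <- c(ii, rep.int(st, length(keys)))
      ij <- c(ij, key2state[keys])
      ix <- c(ix, p)
    }
  }

  ns <- length(state_key)
  states <- cbind(q = ((state_key - 1L) %% nq) + 1L,
                  t = ((state_key - 1L) %/% nq) + 1L)
  structure(list(
    states = states,
    P_sim = Matrix::sparseMatrix(i = si, j = sj, x = sx, dims = c(ns, ns)),
    P_ind = Matrix::sparseMatrix(i = ii, j = ij, x = ix, dims = c(ns, ns)),
    support = key2state[sort(unique(support_keys))],
    query_nodes = qn, target_nodes = tn
  ), class = "csrw_chain")
}

adj_list <- function(net) {
  n <- igraph::vcount(net)
  out <- rep(list(list(idx = integer(0), w = numeric(0))), n)
  if (igraph::ecount(net) == 0L) return(out)
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- igraph::E(net)$weight %||% rep(1, nrow(el))
  idx <- c(el[, 1], el[, 2]); nb <- c(el[, 2], el[, 1]); ww <- c(w, w)
  o <- order(idx, nb)
  idx <- idx[o]; nb <- nb[o]; ww <- ww[o]
  split_nb <- split(nb, idx); split_w <- split(ww, idx)
  for (k in seq_along(split_nb)) {
    v <- as.integer(names(split_nb)[k])
    out[[v]] <- list(idx = as.integer(split_nb[[k]]), w = split_w[[k]])
  }
  out
}

#' @export
print.csrw_chain <- function(x, ...) {
  cat("csrw_chain:", nrow(x$states), "pair states (",
      length(x$query_nodes), "query x", length(x$target_nodes),
      "target nodes ),", length(x$support), "support states\n")
  invisible(x)
}

#' Stationary simultaneous-visit rates of a CSRW chain
#'
#' Runs the power method on the lazy chain starting from the uniform
#' distribution over the positive-similarity support, until the L1 change
#' falls below `tol` or `max_iter` iterations. The correspondence score of
#' a pair is its stationary rate of *simultaneous* arrivals, i.e. the
#' `P_sim` share of incoming probability flow at convergence.
#'
#' For reducible chains the limit depends on the initial support; this is
#' accepted (the walk has no teleportation term).
#'
#' @param chain a `csrw_chain`
#' @param tol L1 convergence tolerance (> 0)
#' @param max_iter maximum number of iterations (>= 1)
#' @param laziness lazy-update weight `a` in `[0, 1)`; any positive value
#'   guarantees aperiodicity and leaves the stationary distribution
#'   unchanged
#' @return a `|V_Q| x |V_T|` dense correspondence matrix with query and
#'   target node ids as dimnames; entries are nonnegative and sum to at
#'   most 1. Attributes: `converged`, `iterations`, `max_prob_dev` (worst
#'   deviation of the iterate's total mass from 1), `stationary` (the full
#'   stationary vector over pair states), `states`.
#' @export
steady_state <- function(chain, tol = 1e-10, max_iter = 10000L, laziness = 0.5) {
  stopifnot(inherits(chain, "csrw_chain"), tol > 0, max_iter >= 1,
            laziness >= 0, laziness < 1)
  ns <- nrow(chain$states)
  P <- chain$P_sim + chain$P_ind
  p <- numeric(ns)
  p[chain$support] <- 1 / length(chain$support)
  converged <- FALSE
  max_dev <- abs(sum(p) - 1)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    pn <- laziness * p + (1 - laziness) * as.numeric(Matrix::crossprod(P, p))
    max_dev <- max(max_dev, abs(sum(pn) - 1))
    delta <- sum(abs(pn - p))
    p <- pn
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("power method did not converge in ", max_iter, " iterations")
  }
  cvec <- as.numeric(Matrix::crossprod(chain$P_sim, p))
  C <- matrix(0, length(chain$query_nodes), length(chain$target_nodes),
              dimnames = list(chain$query_nodes, chain$target_nodes))
  C[chain$states] <- cvec
  structure(C, converged = converged, iterations = iter,
            max_prob_dev = max_dev, stationary = p, states = chain$states)
}

#' Node correspondence between a query and a target network
#'
#' Convenience composition of [build_chain()] and [steady_state()] using
#' the `csrw.*` configuration keys.
#'
#' @param query,target igraph networks
#' @param sim a [similarity_table]
#' @param config configuration list, see [default_config()]
#' @return correspondence matrix as returned by [steady_state()]
#' @export
correspondence <- function(query, target, sim, config = default_config()) {
  chain <- build_chain(query, target, sim)
  steady_state(chain,
               tol = config[["csrw.tol"]],
               max_iter = config[["csrw.max_iter"]],
               laziness = config[["csrw.laziness"]])
}
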