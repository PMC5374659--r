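# Synthetic benchmark generator: implant a perturbed copy of a random
# connected query module into a random background network, with a
# BLAST-bit-score-like similarity signal and known ground truth.

#' Configuration for the synthetic benchmark generator
#'
#' @param query_size number of nodes of the query module (>= 1)
#' @param background_size number of nodes of the background target graph
#' @param background_model `"erdos_renyi"` (sparse, edge probability set
#'   for mean degree 4 by default, like real PPI networks) or
#'   `"preferential_attachment"` (degree-heterogeneous)
#' @param er_p Erdős–Rényi edge probability; default `4 / (n - 1)`
#' @param pa_m edges per added node for preferential attachment (default 2)
#' @param p_node_delete probability that a copied query node is deleted
#'   from the implant
#' @param p_node_insert `ceiling(p_node_insert * query_size)` extra nodes
#'   are inserted into the implant
#' @param p_edge_rewire probability that a copied edge is rewired
#' @param homolog_score_mean,homolog_score_sd truncated-normal parameters
#'   of the positive similarity score given to each surviving
#'   query-homolog pair (bit-score scale; defaults 50 and 10)
#' @param spurious_pair_rate probability that a non-homolog query-target
#'   pair receives a positive score (drawn with mean
#'   `homolog_score_mean / 4`)
#' @param rng_seed integer seed; all sampling derives from it
#' @return object of class `synth_config`
#' @export
synth_config <- function(query_size = 10L, background_size = 300L,
                         background_model = c("erdos_renyi",
                                              "preferential_attachment"),
                         er_p = NULL, pa_m = 2L,
                         p_node_delete = 0, p_node_insert = 0,
                         p_edge_rewire = 0,
                         homolog_score_mean = 50, homolog_score_sd = 10,
                         spurious_pair_rate = 0, rng_seed = 1L) {
  background_model <- match.arg(background_model)
  stopifnot(query_size >= 1, background_size >= 1,
            p_node_delete >= 0, p_node_delete <= 1,
            p_node_insert >= 0, p_node_insert <= 1,
            p_edge_rewire >= 0, p_edge_rewire <= 1,
            spurious_pair_rate >= 0, spurious_pair_rate <= 1,
            homolog_score_mean > 0, homolog_score_sd >= 0)
  structure(list(query_size = as.integer(query_size),
                 background_size = as.integer(background_size),
                 background_model = background_model,
                 er_p = er_p, pa_m = as.integer(pa_m),
                 p_node_delete = p_node_delete,
                 p_node_insert = p_node_insert,
                 p_edge_rewire = p_edge_rewire,
                 homolog_score_mean = homolog_score_mean,
                 homolog_score_sd = homolog_score_sd,
                 spurious_pair_rate = spurious_pair_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "synth_config")
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

rtruncnorm_pos <- function(n, mean, sd) {
  if (n == 0L) return(numeric())
  out <- rnorm(n, mean, sd)
  while (any(bad <- out <= 0)) out[bad] <- rnorm(sum(bad), mean, sd)
  out
}

#' Generate a synthetic query/target/similarity triple with ground truth
#'
#' Emulates the conserved-module setting: a connected query module is
#' sampled, a perturbed copy of it (node deletions, node insertions, edge
#' rewiring) is implanted into a sparse random background graph and
#' attached by at least one bridge edge, and a similarity table is built
#' from a strong truncated-normal signal on surviving homolog pairs plus
#' spurious positive scores on random non-homolog pairs.
#'
#' Node id schema: query nodes `Q01...`, implanted homologs `M01...`
#' (`Mk` is the homolog of `Qk`), inserted nodes `I01...`, background
#' nodes `B001...`.
#'
#' @param cfg a [synth_config]
#' @return list with elements `query` (igraph), `target` (igraph), `sim`
#'   (a [similarity_table]) and `truth` (class `ground_truth`: `map`,
#'   a named vector homolog map query -> target; `implanted_nodes`;
#'   `implanted_edges`; `inserted_nodes`; `bridge_edges`)
#' @export
generate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_local_seed(cfg$rng_seed, {
    nq <- cfg$query_size
    qn <- sprintf("Q%02d", seq_len(nq))

    # connected query module, mean degree ~3
    repeat {
      qg <- igraph::sample_gnp(nq, p = min(1, 3 / max(1, nq - 1)))
      if (igraph::is_connected(qg)) break
    }
    qe <- igraph::as_edgelist(qg, names = FALSE)
    query <- make_network(
      if (nrow(qe)) data.frame(from = qn[qe[, 1]], to = qn[qe[, 2]],
                               stringsAsFactors = FALSE) else NULL,
      nodes = qn)

    # background graph
    nb <- cfg$background_size
    bn <- sprintf("B%03d", seq_len(nb))
    bg <- switch(cfg$background_model,
      erdos_renyi = igraph::sample_gnp(nb, p = cfg$er_p %||%
                                         min(1, 4 / max(1, nb - 1))),
      preferential_attachment = igraph::sample_pa(nb, m = cfg$pa_m,
                                                  directed = FALSE))
    be <- igraph::as_edgelist(bg, names = FALSE)

    # implant: copy of the query with deletions / insertions / rewiring
    survive <- runif(nq) >= cfg$p_node_delete
    if (!any(survive)) {
      stop("infeasible config: every implanted node was deleted")
    }
    mn <- sprintf("M%02d", seq_len(nq))
    surv_nodes <- mn[survive]
    imp_from <- character(); imp_to <- character()
    if (nrow(qe)) {
      keep_e <- survive[qe[, 1]] & survive[qe[, 2]]
      ea <- mn[qe[keep_e, 1]]; eb <- mn[qe[keep_e, 2]]
      # rewire: detach one endpoint, reattach to another surviving node
      for (i in seq_along(ea)) {
        if (runif(1) < cfg$p_edge_rewire && length(surv_nodes) > 2L) {
          keep_end <- if (runif(1) < 0.5) ea[i] else eb[i]
          cand <- setdiff(surv_nodes, c(ea[i], eb[i]))
          newb <- cand[sample.int(length(cand), 1L)]
          ea[i] <- keep_end; eb[i] <- newb
        }
      }
      imp_from <- ea; imp_to <- eb
    }
    n_ins <- ceiling(cfg$p_node_insert * nq)
    ins_nodes <- if (n_ins > 0) sprintf("I%02d", seq_len(n_ins)) else character()
    for (v in ins_nodes) {
      k <- min(2L, length(surv_nodes))
      anchors <- surv_nodes[sample.int(length(surv_nodes), k)]
      imp_from <- c(imp_from, rep(v, k)); imp_to <- c(imp_to, anchors)
    }
    implant_nodes <- c(surv_nodes, ins_nodes)

    # bridges to the background (>= 1)
    n_bridge <- max(1L, ceiling(0.1 * length(implant_nodes)))
    br_imp <- implant_nodes[sample.int(length(implant_nodes), n_bridge,
                                       replace = TRUE)]
    br_bg <- bn[sample.int(nb, n_bridge, replace = TRUE)]

    target <- make_network(data.frame(
      from = c(bn[be[, 1]], imp_from, br_imp),
      to = c(bn[be[, 2]], imp_to, br_bg),
      stringsAsFactors = FALSE), nodes = c(bn, implant_nodes))

    # similarity: homolog signal + spurious noise
    hq <- qn[survive]; ht <- mn[survive]
    hs <- rtruncnorm_pos(sum(survive), cfg$homolog_score_mean,
                         cfg$homolog_score_sd)
    sq <- character(); st <- character(); ss <- numeric()
    if (cfg$spurious_pair_rate > 0) {
      tn <- net_nodes(target)
      grid_q <- rep(qn, times = length(tn))
      grid_t <- rep(tn, each = nq)
      is_homolog <- grid_t == sprintf("M%02d", match(grid_q, qn)) &
        grid_t %in% ht
      pick <- runif(length(grid_q)) < cfg$spurious_pair_rate & !is_homolog
      if (any(pick)) {
        sq <- grid_q[pick]; st <- grid_t[pick]
        ss <- rtruncnorm_pos(sum(pick), cfg$homolog_score_mean / 4,
                             cfg$homolog_score_sd)
      }
    }
    sim <- similarity_table(c(hq, sq), c(ht, st), c(hs, ss))

    imp_edges <- if (length(imp_from)) {
      cbind(pmin(imp_from, imp_to), pmax(imp_from, imp_to))
    } else matrix(character(), 0, 2)
    truth <- structure(list(
      map = stats::setNames(ht, hq),
      implanted_nodes = implant_nodes,
      implanted_edges = unique(imp_edges),
      inserted_nodes = ins_nodes,
      bridge_edges = cbind(br_imp, br_bg)
    ), class = "ground_truth")

    list(query = query, target = target, sim = sim, truth = truth)
  })
}

#' Recovery score of a querying result against the ground truth
#'
#' The Jaccard [match_score()] between the result's final node set and
#' the implanted module (surviving homologs plus inserted nodes).
#'
#' @param result a [query_result]
#' @param truth a `ground_truth` from [generate_pair()]
#' @return real in `[0, 1]`; 0 if the result is empty
#' @export
recovery_score <- function(result, truth) {
  final <- if (inherits(result, "query_result")) result$final else
    as.character(result)
  if (!length(final)) return(0)
  match_score(final, truth$implanted_nodes)
}
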