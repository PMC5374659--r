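# Normalization of the correspondence matrix and seed selection.

#' Normalize a correspondence matrix
#'
#' Computes `Cbar = (J_L %*% C + C %*% J_R) / 2`, where `J_L` rescales each
#' row of `C` to sum to 1 and `J_R` each column. The normalized score
#' measures the *relative* strength of a pair against all alternatives for
#' its query and target node, making scores comparable across networks of
#' different size. A row or column summing to zero contributes 0 (no
#' division by zero).
#'
#' @param C nonnegative correspondence matrix (query x target)
#' @return matrix `Cbar` of the same shape, entries in `[0, 1]`, with the
#'   diagonal scalings attached as attributes `J_L` and `J_R`
#' @export
normalize_correspondence <- function(C) {
  stopifnot(is.matrix(C), all(C >= 0))
  rs <- rowSums(C); cs <- colSums(C)
  jl <- ifelse(rs > 0, 1 / rs, 0)
  jr <- ifelse(cs > 0, 1 / cs, 0)
  Cbar <- 0.5 * (C * jl + sweep(C, 2L, jr, `*`))
  dimnames(Cbar) <- dimnames(C)
  attr(Cbar, "J_L") <- jl
  attr(Cbar, "J_R") <- jr
  Cbar
}

#' Seed-selection scores for all target nodes
#'
#' For each target node `t` the selection score is
#' `sum_q log(1 - cbar(q, t))` (scores clipped at `1 - 1e-12` before the
#' log). This is the log of the product `prod_q (1 - cbar(q, t))`, which
#' approaches 0 (log approaches -Inf) for target nodes with many strongly
#' corresponding query nodes — lower is better.
#'
#' @param Cbar normalized correspondence matrix
#' @return named numeric vector of log-scores over target nodes
#' @export
seed_scores <- function(Cbar) {
  cl <- pmin(unclass(Cbar), 1 - 1e-12)
  colSums(log1p(-cl))
}

#' Select seed nodes in the target network
#'
#' Ranks target nodes by the [seed_scores()] criterion (ascending) and
#' returns the best `n_q` distinct nodes. Since the score is static
#' between picks, the iterative selection collapses to a single ranking.
#' Ties are broken by larger maximum per-column normalized score, then by
#' lexicographic node id.
#'
#' @param Cbar normalized correspondence matrix (non-empty)
#' @param n_q number of seeds to select (>= 1); capped at the number of
#'   target nodes. Defaults to the query size, so the seed network can
#'   never exceed the query network in size.
#' @return data.frame of class `seed_list` with columns `node`, `score`
#'   (non-decreasing), `max_corr`
#' @export
select_seeds <- function(Cbar, n_q = nrow(Cbar)) {
  stopifnot(ncol(Cbar) >= 1L, n_q >= 1L)
  sc <- seed_scores(Cbar)
  mc <- apply(unclass(Cbar), 2L, max)
  nodes <- colnames(Cbar) %||% as.character(seq_along(sc))
  o <- order(sc, -mc, nodes)
  k <- min(n_q, length(sc))
  out <- data.frame(node = nodes[o][seq_len(k)],
                    score = unname(sc[o][seq_len(k)]),
                    max_corr = unname(mc[o][seq_len(k)]),
                    stringsAsFactors = FALSE)
  class(out) <- c("seed_list", "data.frame")
  out
}
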