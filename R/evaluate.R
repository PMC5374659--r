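# Evaluation metrics for predicted complexes: Jaccard matching score,
# information content, hypergeometric enrichment with BH-FDR, and the
# hit / functionally-coherent-hit / specificity classification.

#' Annotation map: proteins to functional terms
#'
#' Flat protein-to-term annotation with a consistent reverse index. No
#' ontology structure is assumed; if evidence-code or aspect filtering is
#' wanted it must be applied to the table beforehand.
#'
#' @param proteins,terms parallel character vectors, one annotation pair
#'   per element
#' @return object of class `annotation_map` with elements `forward`
#'   (protein -> term set), `reverse` (term -> protein set), `proteins`,
#'   `terms`
#' @export
annotation_map <- function(proteins, terms) {
  proteins <- as.character(proteins); terms <- as.character(terms)
  stopifnot(length(proteins) == length(terms))
  forward <- lapply(split(terms, proteins), unique)
  reverse <- lapply(split(proteins, terms), unique)
  structure(list(forward = forward, reverse = reverse,
                 proteins = sort(names(forward)),
                 terms = sort(names(reverse))),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("annotation_map:", length(x$proteins), "proteins,",
      length(x$terms), "terms\n")
  invisible(x)
}

#' Jaccard matching score between two node sets
#'
#' `|Q intersect C| / |Q union C|`; 1 iff the sets are equal, 0 iff
#' disjoint. Two complexes are conventionally considered a match when the
#' score reaches 0.5.
#'
#' @param Q,C non-empty character vectors of node ids
#' @return real in `[0, 1]`
#' @export
match_score <- function(Q, C) {
  Q <- unique(as.character(Q)); C <- unique(as.character(C))
  if (!length(Q) || !length(C)) stop("match_score requires non-empty sets")
  length(intersect(Q, C)) / length(union(Q, C))
}

#' Count querying results matching a gold-standard reference
#'
#' A result counts as a match when at least one reference complex reaches
#' the matching-score threshold.
#'
#' @param results named list of node-id vectors (predicted complexes)
#' @param reference named list of node-id vectors (gold standard)
#' @param threshold matching-score threshold in `(0, 1]` (default 0.5)
#' @return integer number of matched results
#' @export
count_matches <- function(results, reference, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!length(results) || !length(reference)) return(0L)
  sum(vapply(results, function(q) {
    any(vapply(reference, function(r) match_score(q, r) >= threshold,
               FALSE))
  }, FALSE))
}

#' Information content of an annotation term
#'
#' `IC(g) = -log2(|g| / |root(g)|)` where `|g|` is the number of proteins
#' carrying term `g` and `|root(g)|` the size of the protein universe
#' under the term's root. Rare terms are informative (high IC);
#' ubiquitous terms approach 0. Terms with IC below 2 (annotating more
#' than a quarter of the universe) are conventionally discarded as
#' uninformative.
#'
#' @param term term id
#' @param ann an [annotation_map]
#' @param universe_size size of the root universe; defaults to the number
#'   of annotated proteins in `ann`
#' @return nonnegative real
#' @export
information_content <- function(term, ann, universe_size = NULL) {
  if (!term %in% names(ann$reverse)) stop("unknown term: ", term)
  g <- length(ann$reverse[[term]])
  root <- universe_size %||% length(ann$proteins)
  stopifnot(root >= g, g >= 1)
  -log2(g / root)
}

#' Hypergeometric term-enrichment test with BH-FDR correction
#'
#' For each term with information content at least `ic_min` and at least
#' one annotated protein in `nodes`, tests over-representation with the
#' one-sided hypergeometric tail `P(X >= k)` for `X ~
#' Hypergeometric(N = |background|, K = |term proteins in background|,
#' n = |nodes|)`, then corrects across tested terms with
#' Benjamini-Hochberg. IC is computed against the background as universe.
#'
#' @param nodes character vector of protein ids (subset of `background`)
#' @param ann an [annotation_map]
#' @param background protein universe; defaults to all annotated proteins
#' @param ic_min minimum information content of tested terms (default 2)
#' @return data.frame with columns `term`, `overlap`, `term_size`, `p`,
#'   `q`, sorted by `q`, then larger overlap, then term id
#' @export
enrichment_test <- function(nodes, ann, background = NULL, ic_min = 2) {
  background <- unique(as.character(background %||% ann$proteins))
  if (!length(background)) stop("empty background universe")
  nodes <- unique(as.character(nodes))
  if (!all(nodes %in% background)) {
    warning("dropping ", sum(!nodes %in% background),
            " node(s) outside the background universe")
    nodes <- intersect(nodes, background)
  }
  N <- length(background); n <- length(nodes)
  rows <- lapply(names(ann$reverse), function(tm) {
    prot <- intersect(ann$reverse[[tm]], background)
    K <- length(prot)
    if (K == 0L || -log2(K / N) < ic_min) return(NULL)
    k <- length(intersect(prot, nodes))
    if (k == 0L) return(NULL)
    data.frame(term = tm, overlap = k, term_size = K,
               p = stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(term = character(), overlap = integer(),
                      term_size = integer(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows$q <- stats::p.adjust(rows$p, method = "BH")
  rows[order(rows$q, -rows$overlap, rows$term), , drop = FALSE]
}

top_term <- function(enr) if (nrow(enr)) enr[1L, , drop = FALSE] else NULL

spe_fraction <- function(nodes, term, ann) {
  nodes <- unique(as.character(nodes))
  if (!length(nodes) || is.null(term)) return(NA_real_)
  annotated <- vapply(nodes, function(p) {
    term %in% (ann$forward[[p]] %||% character())
  }, FALSE)
  mean(annotated)
}

#' Classify a querying result as hit / functionally coherent hit
#'
#' Runs the enrichment test for the query module and for the querying
#' result, then derives:
#'
#' * `hit`: the result's most-enriched term (lowest FDR q) is significant
#'   at `p_threshold`.
#' * `SPE` (specificity): fraction of result proteins annotated with the
#'   result's most-enriched term.
#' * `FC_hit`: `hit` with `SPE >= 0.5` (functionally coherent).
#' * `significant_hit`: the *query's* most-enriched term is also enriched
#'   in the result with q below `p_threshold` — the result carries the
#'   query's function.
#' * `significant_SPE`: fraction of result proteins annotated with the
#'   query's most-enriched term.
#' * `significant_FC_hit`: `significant_hit` with `significant_SPE >= 0.5`.
#'
#' Ties for "most enriched" go to the smallest q, then the largest
#' overlap, then the lexicographically smallest term id.
#'
#' @param query_nodes,result_nodes protein-id vectors
#' @param ann an [annotation_map]
#' @param background protein universe (default: all annotated proteins)
#' @param p_threshold FDR significance threshold in `(0, 1)` (default 0.05)
#' @param ic_min minimum information content of tested terms (default 2)
#' @return list with the six flags/fractions above plus `query_term`,
#'   `result_term` and both enrichment tables
#' @export
classify_hits <- function(query_nodes, result_nodes, ann, background = NULL,
                          p_threshold = 0.05, ic_min = 2) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  enr_q <- enrichment_test(query_nodes, ann, background, ic_min)
  enr_r <- enrichment_test(result_nodes, ann, background, ic_min)
  tq <- top_term(enr_q); tr <- top_term(enr_r)

  hit <- !is.null(tr) && tr$q < p_threshold
  spe <- spe_fraction(result_nodes, tr$term %||% NULL, ann)
  fc_hit <- isTRUE(hit && !is.na(spe) && spe >= 0.5)

  sig_q_in_result <- if (!is.null(tq) && tq$term %in% enr_r$term) {
    enr_r$q[match(tq$term, enr_r$term)]
  } else NA_real_
  significant_hit <- !is.na(sig_q_in_result) && sig_q_in_result < p_threshold
  significant_spe <- spe_fraction(result_nodes,
                                  if (is.null(tq)) NULL else tq$term, ann)
  significant_fc_hit <- isTRUE(significant_hit && !is.na(significant_spe) &&
                                 significant_spe >= 0.5)

  list(hit = hit, FC_hit = fc_hit,
       significant_hit = significant_hit,
       significant_FC_hit = significant_fc_hit,
       SPE = spe, significant_SPE = significant_spe,
       query_term = if (is.null(tq)) NA_character_ else tq$term,
       result_term = if (is.null(tr)) NA_character_ else tr$term,
       query_enrichment = enr_q, result_enrichment = enr_r)
}
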