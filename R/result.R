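#' Construct a query result record
#'
#' Bundles everything a querying run produces: the final matched node
#' set, the protected seed nodes, per-node extension rewards, the
#' conductance trace of the extension, and a provenance tag per node
#' (`seed`, `extended`, or `pruned`). Node-indexed vectors are stored
#' sorted by node id so that written and re-read records compare equal.
#'
#' @param query_id identifier string
#' @param final character vector of final member node ids
#' @param seeds character vector of seed node ids
#' @param rewards named nonnegative integer vector (over pre-prune members)
#' @param trace numeric conductance trace
#' @param provenance named character vector with values
#'   `seed`/`extended`/`pruned`
#' @param n_components number of connected components of the final set
#' @return object of class `query_result`
#' @export
query_result <- function(query_id, final, seeds, rewards, trace,
                         provenance, n_components = NA_integer_) {
  stopifnot(all(rewards >= 0), all(seeds %in% names(provenance)))
  o <- order(names(provenance))
  structure(list(
    query_id = as.character(query_id),
    final = sort(unique(as.character(final))),
    seeds = sort(unique(as.character(seeds))),
    rewards = rewards[order(names(rewards))],
    trace = as.numeric(trace),
    provenance = provenance[o],
    n_components = as.integer(n_components)
  ), class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat("query_result '", x$query_id, "': ", length(x$final),
      " node(s) [", length(x$seeds), " seed(s), ",
      sum(x$provenance == "extended"), " extended, ",
      sum(x$provenance == "pruned"), " pruned], ",
      x$n_components, " component(s)\n", sep = "")
  cat("  conductance trace:", paste(signif(x$trace, 4), collapse = " -> "),
      "\n")
  invisible(x)
}

#' Write a query result to a structured text file
#'
#' Key-value header plus a per-node table; [read_result()] restores an
#' identical record.
#'
#' @param result a [query_result]
#' @param path output file path
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "query_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#netquery_result\tv1",
    paste0("query_id\t", result$query_id),
    paste0("trace\t", paste(format_num(result$trace), collapse = ",")),
    paste0("n_components\t", result$n_components),
    "nodes:\tnode\tprovenance\treward\tfinal"
  ), con)
  nodes <- names(result$provenance)
  rw <- ifelse(nodes %in% names(result$rewards),
               result$rewards[nodes], 0L)
  writeLines(paste(nodes, result$provenance, rw,
                   as.integer(nodes %in% result$final), sep = "\t"), con)
  invisible(path)
}

#' Read a query result written by [write_result()]
#' @param path file path
#' @return a [query_result]
#' @export
read_result <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "#netquery_result")) {
    stop("not a netquery result file: ", path)
  }
  hdr_end <- grep("^nodes:", lines)[1]
  hdr <- strsplit(lines[2:(hdr_end - 1L)], "\t", fixed = TRUE)
  kv <- stats::setNames(vapply(hdr, `[`, "", 2L), vapply(hdr, `[`, "", 1L))
  tab <- strsplit(lines[-seq_len(hdr_end)], "\t", fixed = TRUE)
  nodes <- vapply(tab, `[`, "", 1L)
  prov <- stats::setNames(vapply(tab, `[`, "", 2L), nodes)
  rewards <- stats::setNames(as.integer(vapply(tab, `[`, "", 3L)), nodes)
  final <- nodes[vapply(tab, `[`, "", 4L) == "1"]
  trace <- if (nzchar(kv[["trace"]])) {
    as.numeric(strsplit(kv[["trace"]], ",", fixed = TRUE)[[1]])
  } else numeric()
  query_result(query_id = kv[["query_id"]],
               final = final,
               seeds = nodes[prov == "seed"],
               rewards = rewards,
               trace = trace,
               provenance = prov,
               n_components = as.integer(kv[["n_components"]]))
}
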