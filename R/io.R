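# Readers/writers for the plain-text interchange formats:
#   network TSV:     node_a<TAB>node_b[<TAB>weight]   ('#' comments ignored)
#   similarity TSV:  query_id<TAB>target_id<TAB>score
#   complexes (GMT): name<TAB>member1<TAB>member2...
#   annotations TSV: protein_id<TAB>term_id

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("cannot open '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a network from a tab-separated edge list
#'
#' Each non-comment line is `node_a<TAB>node_b[<TAB>weight]`. A missing
#' weight defaults to 1. Duplicate edges (in either node order) collapse
#' keeping the maximum weight; self-loops are dropped with a warning.
#'
#' @param path file path
#' @param directed_input if `TRUE` the file is understood to list each
#'   interaction in both orientations; the result is undirected either way
#'   and reciprocal rows merge like any other duplicate.
#' @return an undirected igraph network (see [make_network()])
#' @export
read_network <- function(path, directed_input = FALSE) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) return(make_network())
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    stop("malformed network row at line ", tl$lineno[bad[1]],
         ": expected 2 or 3 tab-separated fields")
  }
  from <- vapply(parts, `[`, "", 1L)
  to <- vapply(parts, `[`, "", 2L)
  w <- rep(1, length(parts))
  has_w <- nf == 3L
  if (any(has_w)) {
    wraw <- suppressWarnings(as.numeric(vapply(parts[has_w], `[`, "", 3L)))
    bad <- which(has_w)[is.na(wraw) | wraw <= 0]
    if (length(bad)) {
      stop("malformed network row at line ", tl$lineno[bad[1]],
           ": weight must be a positive number")
    }
    w[has_w] <- wraw
  }
  make_network(data.frame(from = from, to = to, weight = w,
                          stringsAsFactors = FALSE))
}

#' Write a network as a tab-separated edge list
#'
#' Emits the canonical edge table of [net_edges()] (three columns:
#' node_a, node_b, weight). Isolated nodes have no edge-list
#' representation and are not written.
#'
#' @param net an igraph network
#' @param path output file path
#' @export
write_network <- function(net, path) {
  ed <- net_edges(net)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# node_a\tnode_b\tweight", con)
  if (nrow(ed)) {
    writeLines(paste(ed$from, ed$to, format_num(ed$weight), sep = "\t"), con)
  }
  invisible(path)
}

format_num <- function(x) {
  vapply(x, function(v) {
    if (is.infinite(v)) return(ifelse(v > 0, "Inf", "-Inf"))
    format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, "")
}

#' Read a node-similarity table
#'
#' Lines are `query_id<TAB>target_id<TAB>score`. Non-positive scores are
#' skipped with a warning; duplicates keep the maximum score.
#'
#' @param path file path
#' @return a [similarity_table]
#' @export
read_similarity <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) return(similarity_table())
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("malformed similarity row at line ", tl$lineno[bad[1]],
         ": expected 3 tab-separated fields")
  }
  sc <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  bad <- which(is.na(sc))
  if (length(bad)) {
    stop("malformed similarity row at line ", tl$lineno[bad[1]],
         ": non-numeric score")
  }
  similarity_table(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L), sc)
}

#' Read a reference complex set (GMT-like)
#'
#' Each line is `name<TAB>member1<TAB>member2...`. Every complex must have
#' at least one member.
#'
#' @param path file path
#' @return named list of character vectors of member ids
#' @export
read_complexes <- function(path) {
  tl <- read_tsv_lines(path)
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("empty complex at line ", tl$lineno[bad[1]],
         ": every complex needs at least one member")
  }
  out <- lapply(parts, function(p) unique(p[-1L]))
  names(out) <- vapply(parts, `[`, "", 1L)
  out
}

#' Write a complex set in the GMT-like format accepted by [read_complexes()]
#' @param complexes named list of character vectors
#' @param path output file path
#' @export
write_complexes <- function(complexes, path) {
  lines <- vapply(seq_along(complexes), function(i) {
    paste(c(names(complexes)[i], complexes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat protein-to-term annotation table
#'
#' Lines are `protein_id<TAB>term_id`, one pair per line. The table is
#' assumed to be already filtered (e.g. to experimental evidence codes);
#' no ontology propagation is performed.
#'
#' @param path file path
#' @return an [annotation_map]
#' @export
read_annotations <- function(path) {
  tl <- read_tsv_lines(path)
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("malformed annotation row at line ", tl$lineno[bad[1]],
         ": expected 2 tab-separated fields")
  }
  annotation_map(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
}
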