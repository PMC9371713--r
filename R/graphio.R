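#' Construct a directed network
#'
#' The basic container used throughout the package: a set of node labels and a
#' deduplicated set of directed edges. Node labels are opaque strings (never
#' coerced to integers), mutual connections are stored as two directed edges,
#' and self-loops are permitted.
#'
#' @param edges two-column character matrix or data frame of (source, target)
#'   pairs; may have zero rows.
#' @param nodes optional character vector of node labels; the union of edge
#'   endpoints is always included, so this only adds isolated nodes.
#' @param allow_self_loops if `FALSE`, an edge (v, v) is an error.
#' @return an object of class `hm_network` with elements `nodes` (sorted
#'   character vector) and `edges` (two-column character matrix, sorted
#'   lexicographically by source then target).
#' @export
hm_network <- function(edges = NULL, nodes = NULL, allow_self_loops = TRUE) {
  if (is.null(edges) || NROW(edges) == 0) {
    em <- matrix(character(0), ncol = 2)
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
  }
  if (!allow_self_loops && nrow(em) > 0 && any(em[, 1] == em[, 2])) {
    stop("self-loops are not allowed (allow_self_loops = FALSE)")
  }
  em <- unique(em)
  nodes <- sort(unique(c(as.character(nodes), as.vector(em))))
  if (nrow(em) > 0) {
    em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  }
  dimnames(em) <- list(NULL, c("from", "to"))
  structure(list(nodes = nodes, edges = em), class = "hm_network")
}

#' @export
print.hm_network <- function(x, ...) {
  cat("hm_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' @export
format.hm_network <- function(x, ...) {
  sprintf("hm_network(%d nodes, %d edges)", length(x$nodes), nrow(x$edges))
}

#' Number of nodes / edges in a network
#' @param net an `hm_network`.
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

# edges as a 1-based integer index matrix into net$nodes
edge_index <- function(net) {
  if (nrow(net$edges) == 0) return(matrix(integer(0), ncol = 2))
  cbind(match(net$edges[, 1], net$nodes), match(net$edges[, 2], net$nodes))
}

# rebuild an hm_network from an integer edge index matrix over net$nodes
network_from_index <- function(nodes, idx) {
  if (NROW(idx) == 0) return(hm_network(NULL, nodes = nodes))
  hm_network(cbind(nodes[idx[, 1]], nodes[idx[, 2]]), nodes = nodes)
}

#' Read a directed network from a plain-text edge list
#'
#' Each non-empty, non-comment line holds two whitespace-separated node labels
#' (source, target). A third numeric column (e.g. a weight) is ignored; lines
#' starting with `#` are comments; a single-token line declares an isolated
#' node. Duplicate edges collapse to one (set semantics).
#'
#' @param path file path or connection.
#' @param allow_self_loops if `FALSE`, a self-loop line raises an error that
#'   reports the offending line number.
#' @param symmetrize if `TRUE`, treat the input as undirected and add both
#'   directions for every edge.
#' @return an [hm_network()].
#' @export
read_edge_list <- function(path, allow_self_loops = TRUE, symmetrize = FALSE) {
  lines <- readLines(path)
  edges <- matrix(character(0), ncol = 2)
  singletons <- character(0)
  elist <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(toks) == 1) {
      singletons <- c(singletons, toks)
      next
    }
    if (!allow_self_loops && toks[1] == toks[2]) {
      stop(sprintf("self-loop '%s' at line %d (allow_self_loops = FALSE)",
                   toks[1], i))
    }
    elist[[i]] <- toks[1:2]
  }
  elist <- elist[!vapply(elist, is.null, logical(1))]
  if (length(elist) > 0) {
    edges <- do.call(rbind, elist)
    if (symmetrize) edges <- rbind(edges, edges[, 2:1, drop = FALSE])
  }
  hm_network(edges, nodes = singletons, allow_self_loops = allow_self_loops)
}

#' Write a directed network as a plain-text edge list
#'
#' Edges are written one per line (`source<TAB>target`), sorted
#' lexicographically for bit-exact reproducibility; isolated nodes are written
#' as single-token lines so that `read_edge_list(write_edge_list(net))`
#' round-trips exactly.
#'
#' @param net an [hm_network()].
#' @param path file path or connection.
#' @return `net`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "hm_network"))
  lines <- character(0)
  if (nrow(net$edges) > 0) {
    lines <- paste(net$edges[, 1], net$edges[, 2], sep = "\t")
  }
  isolated <- setdiff(net$nodes, as.vector(net$edges))
  lines <- c(lines, sort(isolated))
  writeLines(lines, path)
  invisible(net)
}

#' Convert between hm_network and igraph
#'
#' @param net an [hm_network()].
#' @return `as_igraph()` returns a directed [igraph::graph]; `from_igraph()`
#'   returns an [hm_network()].
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "hm_network"))
  igraph::graph_from_data_frame(as.data.frame(net$edges),
                                directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}

#' @rdname as_igraph
#' @param g a directed igraph object.
#' @export
from_igraph <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  storage.mode(el) <- "character"
  hm_network(el, nodes = igraph::V(g)$name)
}

#' Read / write GraphML
#'
#' Thin wrappers over igraph's GraphML support, returning/accepting the
#' package's network container.
#'
#' @param path file path.
#' @return `read_graphml()` returns an [hm_network()].
#' @export
read_graphml <- function(path) {
  from_igraph(igraph::read_graph(path, format = "graphml"))
}

#' @rdname read_graphml
#' @param net an [hm_network()].
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(net)
}
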