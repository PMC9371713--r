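# Synthetic directed networks with controlled motif and motif-combination
# content: a uniform random background plus planted pattern copies with a
# ground-truth manifest, so census and enrichment can be validated end to end.

#' Uniform random directed background network
#'
#' Samples a simple digraph with exactly `m` edges uniformly among all simple
#' digraphs on `n` labeled nodes (no self-loops unless enabled).
#'
#' @param n node count.
#' @param m edge count (`<= n * (n - 1)`, or `n^2` with self-loops).
#' @param seed integer seed.
#' @param allow_self_loops include the diagonal in the candidate edge space.
#' @return an [hm_network()] with nodes `v1..vn`.
#' @export
generate_background <- function(n, m, seed, allow_self_loops = FALSE) {
  max_m <- if (allow_self_loops) n * n else n * (n - 1)
  if (m > max_m) stop("m = ", m, " exceeds the ", max_m, " possible edges")
  nodes <- sprintf("v%d", seq_len(n))
  if (m == 0) return(hm_network(NULL, nodes = nodes))
  set.seed(seed)
  pick <- sample.int(max_m, m)
  if (allow_self_loops) {
    src <- (pick - 1) %/% n + 1
    tgt <- (pick - 1) %% n + 1
  } else {
    src <- (pick - 1) %/% (n - 1) + 1
    off <- (pick - 1) %% (n - 1) + 1
    tgt <- ifelse(off >= src, off + 1, off)
  }
  hm_network(cbind(nodes[src], nodes[tgt]), nodes = nodes)
}

# built-in plantable patterns: adjacency plus the motif instances (in
# canonical position order) that the pattern contains by construction
planted_pattern <- function(name) {
  ffl <- get_motif("FFL")
  switch(name,
    FFL = list(
      adj = ffl$adj,
      motifs = list(list(motif = "FFL", positions = c(1, 2, 3)))
    ),
    # two FFLs chained output-to-input: the output node of the first is the
    # input node of the second (the layered cascade arrangement)
    ffl_cascade = list(
      adj = mk_adj(5, list(c(1, 2), c(1, 3), c(2, 3),
                           c(3, 4), c(3, 5), c(4, 5))),
      motifs = list(list(motif = "FFL", positions = c(1, 2, 3)),
                    list(motif = "FFL", positions = c(3, 4, 5)))
    ),
    stop("unknown planted pattern '", name, "'")
  )
}

#' Plant pattern copies into a network
#'
#' Inserts `copies` disjoint copies of a pattern (a named built-in such as
#' `"FFL"` or `"ffl_cascade"`, or a custom adjacency matrix) into the
#' network. By default each copy uses fresh nodes (labelled
#' `p<copy>_<position>`) so no accidental patterns are created; with
#' `reuse = "background"` each copy is wired onto randomly chosen existing
#' nodes instead.
#'
#' @param net an [hm_network()] to plant into.
#' @param pattern pattern name or adjacency matrix.
#' @param copies number of copies.
#' @param seed integer seed (used by the `"background"` reuse policy).
#' @param reuse `"fresh"` (default) or `"background"`.
#' @return list with `network` (the augmented [hm_network()]) and `manifest`
#'   (data frame: `copy`, `motif`, `nodes` — comma-joined node labels of each
#'   planted motif instance in canonical position order; for custom
#'   adjacency patterns, one row per copy with `motif = "custom"`).
#' @export
plant_patterns <- function(net, pattern, copies, seed = 1, reuse = "fresh") {
  reuse <- match.arg(reuse, c("fresh", "background"))
  if (is.character(pattern)) {
    pat <- planted_pattern(pattern)
  } else {
    pat <- list(adj = as.matrix(pattern), motifs = list())
  }
  kp <- nrow(pat$adj)
  set.seed(seed)
  edges <- net$edges
  nodes <- net$nodes
  manifest <- list()
  for (cp in seq_len(copies)) {
    if (reuse == "fresh") {
      labs <- sprintf("p%d_%d", cp, seq_len(kp))
    } else {
      if (length(nodes) < kp) stop("node budget exhausted for planting")
      labs <- sample(nodes, kp)
    }
    nodes <- union(nodes, labs)
    ee <- which(pat$adj == 1, arr.ind = TRUE)
    edges <- rbind(edges, cbind(labs[ee[, 1]], labs[ee[, 2]]))
    if (length(pat$motifs) > 0) {
      for (mi in pat$motifs) {
        # order the instance nodes canonically, matching the census
        # convention (canonical positions, lexicographic tie-break)
        sub <- pat$adj[mi$positions, mi$positions, drop = FALSE]
        P <- canonical_perms(sub)
        cand <- matrix(labs[mi$positions][t(P)], ncol = ncol(P), byrow = TRUE)
        tup <- cand[do.call(order, as.data.frame(cand))[1], ]
        manifest[[length(manifest) + 1]] <- data.frame(
          copy = cp, motif = mi$motif,
          nodes = paste(tup, collapse = ","),
          stringsAsFactors = FALSE)
      }
    } else {
      manifest[[length(manifest) + 1]] <- data.frame(
        copy = cp, motif = "custom",
        nodes = paste(labs, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  list(network = hm_network(edges, nodes = nodes),
       manifest = do.call(rbind, manifest))
}

#' Synthetic validation network with planted FFL cascades
#'
#' Convenience generator for the standard validation setting: a sparse
#' uniform background plus planted copies of the output-to-input FFL cascade
#' combination, the arrangement in which the output node of one feedforward
#' loop serves as the input of the next.
#'
#' @param n_background,m_background background size.
#' @param copies planted cascade copies.
#' @param seed integer seed.
#' @return as [plant_patterns()].
#' @export
synthetic_cascade_network <- function(n_background = 150, m_background = 300,
                                      copies = 30, seed = 1) {
  bg <- generate_background(n_background, m_background, seed = seed)
  plant_patterns(bg, "ffl_cascade", copies = copies, seed = seed + 1)
}
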