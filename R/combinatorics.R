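# Counting and enumerating the ways two motifs can be joined: combinations
# (shared nodes) and interactions (cross-linking edges), including core
# topologies and their edge extensions.

#' Maximal number of shared nodes in a motif combination
#'
#' Two motifs of sizes nA and nB can share at most `min(nA, nB) - 1` nodes:
#' sharing any more would collapse the smaller motif entirely into the larger
#' one, destroying the autonomy of its topology.
#'
#' @param nA,nB motif sizes (each >= 2).
#' @return integer.
#' @export
max_shared_nodes <- function(nA, nB) {
  if (nA < 2 || nB < 2) stop("motif sizes must be at least 2")
  min(nA, nB) - 1L
}

#' Maximal number of linking edges in a motif interaction
#'
#' Every pair of nodes that do not participate in the same motif can be
#' linked, giving `nA * nB` pairs, doubled for directed networks where each
#' pair supports two directed edges.
#'
#' @param nA,nB motif sizes (each >= 1).
#' @param directed doubled when `TRUE`.
#' @return integer.
#' @export
max_linking_edges <- function(nA, nB, directed = TRUE) {
  stopifnot(nA >= 1, nB >= 1)
  nA * nB * (if (directed) 2L else 1L)
}

#' Number of possible interaction topologies between two motifs
#'
#' Counts the labeled subsets of admissible cross-edges: `2^(2 nA nB)` for
#' directed networks and `2^(nA nB)` for undirected ones. The count includes
#' the empty (no-edge) case; set `nonempty = TRUE` to drop it, matching the
#' definition of an interaction as at least one linking edge. Isomorphic
#' duplicates are not removed here (see [enumerate_extensions()] for
#' deduplicated enumeration on concrete motifs).
#'
#' @inheritParams max_linking_edges
#' @param nonempty drop the zero-edge configuration.
#' @return a numeric count (can exceed integer range for larger motifs).
#' @export
count_interaction_topologies <- function(nA, nB, directed = TRUE,
                                         nonempty = FALSE) {
  stopifnot(nA >= 1, nB >= 1)
  2^(max_linking_edges(nA, nB, directed)) - (if (nonempty) 1 else 0)
}

#' Enumerate core combination topologies of two motifs
#'
#' Enumerates every topologically distinct way motifs A and B can be joined
#' by sharing `Nv` nodes, for all admissible `1 <= Nv <= min(nA, nB) - 1`.
#' All assignments of shared positions are scanned and the resulting merged
#' graphs are deduplicated up to isomorphism, which also identifies patterns
#' related by exchanging A and B when the two motifs are the same class.
#'
#' By default each motif must remain an *induced* occurrence on its
#' designated nodes of the merged graph (`strict = TRUE`): merges in which
#' the other motif's edges add connections inside a motif's own node set are
#' excluded, preserving the autonomy of each motif's topology. With
#' `strict = FALSE` such merges are kept as long as each motif's own edges
#' realize it as a (not necessarily induced) subgraph. The number of
#' assignments excluded by the strict rule is attached as attribute
#' `"excluded"`.
#'
#' @param motifA,motifB [motif_class()] objects (sizes <= 4).
#' @param strict require induced occurrences (see Details).
#' @return a list of combination patterns, each a list with `motifA`,
#'   `motifB`, `shared_a`, `shared_b` (position vectors), `nv`, `notation`
#'   (e.g. `"FFL{output}*FFL{input}"`), `adj` (merged adjacency matrix),
#'   `nodes_a`, `nodes_b` (merged-graph indices of each motif) and `key`.
#' @export
enumerate_combinations <- function(motifA, motifB, strict = TRUE) {
  stopifnot(inherits(motifA, "hm_motif"), inherits(motifB, "hm_motif"),
            motifA$size <= 4, motifB$size <= 4)
  A <- motifA$adj
  B <- motifB$adj
  nA <- nrow(A)
  nB <- nrow(B)
  rolesA <- role_partition(motifA)
  rolesB <- role_partition(motifB)
  out <- list()
  seen <- character(0)
  excluded <- 0L
  for (nv in seq_len(max_shared_nodes(nA, nB))) {
    selA <- ordered_tuples(nA, nv)
    selB <- ordered_tuples(nB, nv)
    for (ia in seq_len(nrow(selA))) {
      for (ib in seq_len(nrow(selB))) {
        a <- selA[ia, ]
        b <- selB[ib, ]
        merged <- merge_motifs(A, B, a, b)
        if (strict) {
          okA <- all(merged$adj[merged$nodes_a, merged$nodes_a] == A)
          okB <- all(merged$adj[merged$nodes_b, merged$nodes_b] == B)
          if (!okA || !okB) {
            excluded <- excluded + 1L
            next
          }
        }
        key <- canonical_form(merged$adj)
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1]] <- list(
          motifA = motifA, motifB = motifB,
          shared_a = a, shared_b = b, nv = nv,
          notation = combination_notation(motifA, rolesA, a,
                                          motifB, rolesB, b),
          adj = merged$adj,
          nodes_a = merged$nodes_a, nodes_b = merged$nodes_b,
          key = key
        )
      }
    }
  }
  attr(out, "excluded") <- excluded
  out
}

# merge B onto A, identifying B positions b with A positions a
merge_motifs <- function(A, B, a, b) {
  nA <- nrow(A)
  nB <- nrow(B)
  nv <- length(a)
  mapB <- integer(nB)
  mapB[b] <- a
  fresh <- setdiff(seq_len(nB), b)
  mapB[fresh] <- nA + seq_along(fresh)
  ntot <- nA + nB - nv
  M <- matrix(0L, ntot, ntot)
  M[seq_len(nA), seq_len(nA)] <- A
  for (i in seq_len(nB)) {
    for (j in seq_len(nB)) {
      if (B[i, j] == 1) M[mapB[i], mapB[j]] <- 1L
    }
  }
  list(adj = M, nodes_a = seq_len(nA), nodes_b = mapB)
}

ordered_tuples <- function(n, k) {
  if (k == 1) return(matrix(seq_len(n), ncol = 1))
  P <- all_perms(n)
  unique(P[, seq_len(k), drop = FALSE])
}

combination_notation <- function(motifA, rolesA, a, motifB, rolesB, b) {
  lab <- function(roles, positions) {
    vapply(positions, function(p) {
      oi <- which(vapply(roles$orbits, function(o) p %in% o, logical(1)))
      roles$labels[[oi]]
    }, character(1))
  }
  sprintf("%s{%s}*%s{%s}",
          motifA$name, paste(lab(rolesA, a), collapse = ","),
          motifB$name, paste(lab(rolesB, b), collapse = ","))
}

#' Enumerate edge extensions of a combination core topology
#'
#' A core combination can be extended by adding any subset of admissible
#' cross-edges, i.e. directed edges between pairs of nodes that do not
#' participate in the same motif. All such supergraphs are enumerated and
#' deduplicated up to isomorphism; the core itself (empty extension) is
#' always included.
#'
#' @param pattern one element of [enumerate_combinations()] output.
#' @return list of merged adjacency matrices, deduplicated; the first element
#'   is the core.
#' @export
enumerate_extensions <- function(pattern) {
  M <- pattern$adj
  only_a <- setdiff(pattern$nodes_a, pattern$nodes_b)
  only_b <- setdiff(pattern$nodes_b, pattern$nodes_a)
  cand <- list()
  for (u in only_a) {
    for (v in only_b) {
      if (M[u, v] == 0) cand[[length(cand) + 1]] <- c(u, v)
      if (M[v, u] == 0) cand[[length(cand) + 1]] <- c(v, u)
    }
  }
  nc <- length(cand)
  if (nc > 16) stop("too many admissible cross-edges (", nc, ") to enumerate")
  out <- list(M)
  seen <- canonical_form(M)
  if (nc == 0) return(out)
  for (mask in seq_len(2^nc - 1)) {
    Mx <- M
    for (bit in seq_len(nc)) {
      if (bitwAnd(mask, bitwShiftL(1L, bit - 1L)) != 0) {
        e <- cand[[bit]]
        Mx[e[1], e[2]] <- 1L
      }
    }
    key <- canonical_form(Mx)
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- Mx
  }
  out
}

#' Enumerate interaction patterns between two motifs
#'
#' Enumerates nonempty subsets of admissible cross-edges between disjoint
#' copies of motifs A and B (up to `2 nA nB` directed candidates), optionally
#' deduplicated by isomorphism of the linked graph.
#'
#' @inheritParams enumerate_combinations
#' @param unique deduplicate by isomorphism of the merged graph.
#' @param max_edges restrict to subsets of at most this many linking edges
#'   (`Inf` for all; the full directed space for two 3-node motifs has 2^18
#'   subsets).
#' @return list of patterns, each with `adj`, `links` (matrix of directed
#'   cross-edges as merged-graph indices) and `key`.
#' @export
enumerate_interactions <- function(motifA, motifB, unique = TRUE,
                                   max_edges = 2) {
  stopifnot(inherits(motifA, "hm_motif"), inherits(motifB, "hm_motif"))
  A <- motifA$adj
  B <- motifB$adj
  nA <- nrow(A)
  nB <- nrow(B)
  ntot <- nA + nB
  M0 <- matrix(0L, ntot, ntot)
  M0[seq_len(nA), seq_len(nA)] <- A
  M0[nA + seq_len(nB), nA + seq_len(nB)] <- B
  cand <- list()
  for (u in seq_len(nA)) {
    for (v in nA + seq_len(nB)) {
      cand[[length(cand) + 1]] <- c(u, v)
      cand[[length(cand) + 1]] <- c(v, u)
    }
  }
  nc <- length(cand)
  sizes <- seq_len(min(max_edges, nc))
  out <- list()
  seen <- character(0)
  for (sz in sizes) {
    picks <- combn(nc, sz)
    for (ci in seq_len(ncol(picks))) {
      Mx <- M0
      links <- do.call(rbind, cand[picks[, ci]])
      Mx[links] <- 1L
      if (unique) {
        key <- canonical_form(Mx)
        if (key %in% seen) next
        seen <- c(seen, key)
      } else {
        key <- canonical_form(Mx)
      }
      out[[length(out) + 1]] <- list(adj = Mx, links = links, key = key)
    }
  }
  out
}
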