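# Exact enumeration of connected k-node induced subgraphs, their isomorphism
# classes, and count-based motif significance against a degree-preserving
# switching null. The k = 3 path runs through compiled code; other sizes use
# a direct subset scan.

# 3-node triad code (compiled convention) -> adjacency matrix
code_to_adj <- function(code) {
  A <- matrix(0L, 3, 3)
  bits <- list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  for (b in seq_along(bits)) {
    if (bitwAnd(code, bitwShiftL(1L, b - 1L)) != 0) {
      A[bits[[b]][1], bits[[b]][2]] <- 1L
    }
  }
  A
}

#' Enumerate connected k-node induced subgraphs
#'
#' Finds every weakly-connected induced k-node subgraph of a directed network
#' and groups the occurrences by isomorphism class. Occurrences are
#' position-normalized: each instance lists its nodes in the canonical
#' position order of the class representative, with ties among automorphic
#' orderings broken by the lexicographically smallest node tuple, so every
#' occurrence appears exactly once. Self-loops are ignored for
#' classification.
#'
#' @param net an [hm_network()].
#' @param k subgraph size (k >= 2; the k = 3 case has a fast exact path).
#' @return a named list keyed by canonical class key; each element has
#'   `motif` (an [motif_class()]) and `instances` (character matrix, one row
#'   per occurrence, columns = canonical positions).
#' @export
enumerate_connected_subgraphs <- function(net, k) {
  stopifnot(inherits(net, "hm_network"), k >= 2)
  n <- n_nodes(net)
  if (k > n) return(structure(list(), names = character(0)))
  if (k == 3) {
    res <- cpp_triad_census(n, edge_index(net), instances = TRUE)
    inst <- res$instances
    if (nrow(inst) == 0) return(structure(list(), names = character(0)))
    by_code <- split(seq_len(nrow(inst)), inst[, 4])
    out <- lapply(by_code, function(rows) {
      code <- inst[rows[1], 4]
      motif <- motif_class(code_to_adj(code))
      m <- matrix(net$nodes[t(inst[rows, 1:3, drop = FALSE])],
                  ncol = 3, byrow = TRUE)
      m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
      list(motif = motif, instances = m)
    })
    names(out) <- vapply(out, function(x) x$motif$key, character(1))
    return(out[order(names(out))])
  }
  enumerate_generic(net, k)
}

# subset-scan enumeration for arbitrary k (exact; intended for small graphs)
enumerate_generic <- function(net, k) {
  n <- n_nodes(net)
  idx <- edge_index(net)
  A <- matrix(0L, n, n)
  if (nrow(idx) > 0) A[idx] <- 1L
  diag(A) <- 0L
  sk <- (A + t(A)) > 0
  if (choose(n, k) > 5e5) {
    stop("subset scan over choose(", n, ", ", k, ") subsets is too large; ",
         "downsample the network first")
  }
  subsets <- combn(n, k)
  acc <- new.env(parent = emptyenv())
  for (ci in seq_len(ncol(subsets))) {
    s <- subsets[, ci]
    skx <- sk[s, s, drop = FALSE]
    if (!is_connected_skeleton(skx)) next
    sub <- A[s, s, drop = FALSE]
    key <- canonical_form(sub)
    P <- canonical_perms(sub)
    tuples <- matrix(s[t(P)], ncol = k, byrow = TRUE)
    ord <- do.call(order, as.data.frame(tuples))
    tuple <- tuples[ord[1], ]
    prev <- if (!is.null(acc[[key]])) acc[[key]] else list()
    prev[[length(prev) + 1]] <- tuple
    acc[[key]] <- prev
  }
  keys <- sort(ls(acc))
  out <- lapply(keys, function(key) {
    tuples <- do.call(rbind, acc[[key]])
    rep_tuple <- tuples[1, ]
    sub <- A[rep_tuple, rep_tuple, drop = FALSE]
    motif <- motif_class(canonical_adj(sub))
    m <- matrix(net$nodes[t(tuples)], ncol = k, byrow = TRUE)
    m <- m[do.call(order, as.data.frame(m)), , drop = FALSE]
    list(motif = motif, instances = m)
  })
  names(out) <- keys
  out
}

# weak connectivity of a small boolean skeleton matrix
is_connected_skeleton <- function(sk) {
  k <- nrow(sk)
  seen <- logical(k)
  stack <- 1L
  seen[1] <- TRUE
  while (length(stack) > 0) {
    v <- stack[[1]]
    stack <- stack[-1]
    nb <- which(sk[v, ] & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' Three-node subgraph census counts
#'
#' The vector of counts of all connected three-node subgraph classes, keyed by
#' canonical class key. This is the quantity held fixed by the
#' census-preserving null model.
#'
#' @param net an [hm_network()].
#' @return named integer vector (only classes with nonzero count).
#' @export
triad_census_counts <- function(net) {
  res <- cpp_triad_census(n_nodes(net), edge_index(net), instances = FALSE)
  counts <- res$counts
  codes <- which(counts > 0) - 1L
  if (length(codes) == 0) return(setNames(integer(0), character(0)))
  keys <- vapply(codes, function(code) canonical_form(code_to_adj(code)),
                 character(1))
  setNames(as.integer(counts[codes + 1L]), keys)[order(keys)]
}

#' Degree-preserving randomization by edge switching
#'
#' Produces a randomized copy of the network with the in- and out-degree of
#' every node preserved exactly, via accepted double-edge swaps that never
#' create duplicate edges or new self-loops (existing self-loops are kept in
#' place). The number of accepted swaps defaults to 10 x |edges|.
#'
#' @param net an [hm_network()].
#' @param seed integer seed for the swap sequence.
#' @param nswap number of accepted swaps (default `10 * n_edges(net)`).
#' @return an [hm_network()] with the same nodes and degree sequences.
#' @export
rewire_degree_preserving <- function(net, seed, nswap = NULL) {
  if (is.null(nswap)) nswap <- 10L * n_edges(net)
  idx <- cpp_rewire_degseq(n_nodes(net), edge_index(net),
                           as.integer(nswap), as.integer(seed))
  network_from_index(net$nodes, idx)
}

#' Motif significance by count Z-scores
#'
#' Compares the count of every connected k-node subgraph class to its
#' distribution over an ensemble of degree-preserving randomized networks
#' (edge switching; sample i uses `seed + i`). The Z-score is
#' (observed - null mean) / null sd; classes whose null sd is zero are
#' reported with Z = 0 and flagged degenerate rather than infinite.
#'
#' @param net an [hm_network()].
#' @param k subgraph size (default 3).
#' @param n_random ensemble size (>= 2).
#' @param seed integer seed.
#' @return data frame with columns `key`, `name`, `count`, `null_mean`,
#'   `null_sd`, `z`, `degenerate`.
#' @export
motif_significance <- function(net, k = 3, n_random = 100, seed = 1) {
  stopifnot(n_random >= 2)
  observed <- class_counts(net, k)
  null_counts <- vector("list", n_random)
  changed <- FALSE
  orig_key <- paste(net$edges[, 1], net$edges[, 2], collapse = ";")
  for (i in seq_len(n_random)) {
    rnet <- rewire_degree_preserving(net, seed = seed + i)
    if (!changed) {
      changed <- !identical(paste(rnet$edges[, 1], rnet$edges[, 2],
                                  collapse = ";"), orig_key)
    }
    null_counts[[i]] <- class_counts(rnet, k)
  }
  if (!changed) {
    warning("randomization left the network unchanged: ",
            "degrees fully constrain the topology; Z-scores are degenerate")
  }
  keys <- sort(unique(c(names(observed), unlist(lapply(null_counts, names)))))
  mat <- vapply(null_counts, function(x) {
    v <- setNames(numeric(length(keys)), keys)
    v[names(x)] <- x
    v
  }, numeric(length(keys)))
  mat <- matrix(mat, nrow = length(keys),
                dimnames = list(keys, NULL))
  obs <- setNames(numeric(length(keys)), keys)
  obs[names(observed)] <- observed
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, sd)
  degenerate <- sdv == 0
  z <- ifelse(degenerate, 0, (obs - mu) / sdv)
  data.frame(
    key = keys,
    name = vapply(keys, motif_display_name, character(1)),
    count = as.integer(obs),
    null_mean = mu,
    null_sd = sdv,
    z = z,
    degenerate = degenerate,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

class_counts <- function(net, k) {
  if (k == 3) return(triad_census_counts(net))
  sub <- enumerate_connected_subgraphs(net, k)
  setNames(vapply(sub, function(x) nrow(x$instances), integer(1)), names(sub))
}
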