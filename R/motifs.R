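# Canonical forms, motif classes and role (automorphism-orbit) partitions for
# small directed graphs. All computations are exact: for k <= 4 positions the
# k! permutations are enumerated directly.

# all permutations of 1..k as a matrix with one permutation per row
all_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# adjacency -> off-diagonal bit string: for node pairs (i < j) in
# lexicographic order, the bits A[i, j] then A[j, i] (the same convention as
# the compiled triad code, so canonical keys agree across the two paths)
adj_bits <- function(A) {
  k <- nrow(A)
  bits <- integer(0)
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      bits <- c(bits, A[i, j], A[j, i])
    }
  }
  paste(bits * 1L, collapse = "")
}

#' Canonical key of a small directed graph
#'
#' An order-invariant encoding of a k-node digraph's adjacency structure: the
#' minimum, over all k! node permutations, of the off-diagonal adjacency bit
#' string. Two digraphs receive the same key if and only if they are
#' isomorphic (exact for any k; intended for k <= 4 where k! is tiny).
#' Self-loops are ignored.
#'
#' @param adj square 0/1 adjacency matrix (`adj[i, j] == 1` for an edge
#'   i -> j).
#' @return a string of the form `"k<size>:<bits>"`.
#' @export
canonical_form <- function(adj) {
  adj <- as.matrix(adj)
  k <- nrow(adj)
  stopifnot(k >= 1, ncol(adj) == k)
  diag(adj) <- 0
  P <- all_perms(k)
  keys <- vapply(seq_len(nrow(P)), function(r) {
    p <- P[r, ]
    adj_bits(adj[p, p, drop = FALSE])
  }, character(1))
  sprintf("k%d:%s", k, min(keys))
}

# permutations (rows of all_perms(k)) that achieve the canonical key
canonical_perms <- function(adj) {
  adj <- as.matrix(adj)
  k <- nrow(adj)
  diag(adj) <- 0
  P <- all_perms(k)
  keys <- vapply(seq_len(nrow(P)), function(r) {
    p <- P[r, ]
    adj_bits(adj[p, p, drop = FALSE])
  }, character(1))
  P[keys == min(keys), , drop = FALSE]
}

# canonical representative adjacency matrix
canonical_adj <- function(adj) {
  p <- canonical_perms(adj)[1, ]
  A <- as.matrix(adj)
  diag(A) <- 0
  A[p, p, drop = FALSE]
}

#' Motif classes
#'
#' A motif class is an isomorphism class of a small connected digraph, stored
#' as its canonical adjacency representative plus a display name.
#'
#' @param adj square 0/1 adjacency matrix of one representative.
#' @param name optional display name (e.g. `"FFL"`).
#' @return an object of class `hm_motif` with fields `size`, `adj` (canonical
#'   representative), `key` (canonical key) and `name`.
#' @export
motif_class <- function(adj, name = NULL) {
  adj <- as.matrix(adj)
  stopifnot(nrow(adj) == ncol(adj), all(adj %in% c(0, 1)))
  key <- canonical_form(adj)
  ca <- canonical_adj(adj)
  if (is.null(name)) name <- motif_display_name(key)
  structure(list(size = nrow(adj), adj = ca, key = key, name = name),
            class = "hm_motif")
}

#' @export
print.hm_motif <- function(x, ...) {
  cat(sprintf("hm_motif '%s' (%d nodes, key %s)\n", x$name, x$size, x$key))
  invisible(x)
}

mk_adj <- function(k, edges) {
  A <- matrix(0L, k, k)
  for (e in edges) A[e[1], e[2]] <- 1L
  A
}

# built-in motif dictionary ---------------------------------------------------

motif_defs <- function() {
  list(
    FFL         = mk_adj(3, list(c(1, 2), c(1, 3), c(2, 3))),
    chain       = mk_adj(3, list(c(1, 2), c(2, 3))),
    v_out       = mk_adj(3, list(c(1, 2), c(1, 3))),
    v_in        = mk_adj(3, list(c(1, 3), c(2, 3))),
    cycle3      = mk_adj(3, list(c(1, 2), c(2, 3), c(3, 1))),
    mutual_dyad = mk_adj(2, list(c(1, 2), c(2, 1)))
  )
}

#' Built-in motif library
#'
#' Named motif classes used throughout: `FFL` (feedforward loop), `chain`
#' (three-node cascade), `v_out` (single regulator of two targets), `v_in`
#' (two regulators of one target), `cycle3` (directed three-node loop) and
#' `mutual_dyad` (two mutually connected nodes).
#'
#' @param name motif name; `motif_library()` lists all of them.
#' @return `get_motif()` returns an [motif_class()]; `motif_library()` a named
#'   list of them.
#' @export
get_motif <- function(name) {
  defs <- motif_defs()
  if (!name %in% names(defs)) {
    stop("unknown motif '", name, "'; known: ", paste(names(defs), collapse = ", "))
  }
  motif_class(defs[[name]], name = name)
}

#' @rdname get_motif
#' @export
motif_library <- function() {
  defs <- motif_defs()
  lapply(setNames(names(defs), names(defs)), get_motif)
}

# canonical key -> display name for the built-ins; otherwise the key itself
motif_display_name <- function(key) {
  tbl <- motif_key_table()
  if (key %in% names(tbl)) tbl[[key]] else key
}

motif_key_table <- function() {
  defs <- motif_defs()
  keys <- vapply(defs, canonical_form, character(1))
  setNames(as.list(names(defs)), keys)
}

# orbit labels for the built-in motifs, keyed by canonical key; each entry is
# a function(partition_positions, canonical_adj) -> labels. In practice we
# label orbits by simple degree structure.
orbit_label <- function(motif, positions) {
  A <- motif$adj
  outd <- rowSums(A)
  ind <- colSums(A)
  p <- positions[1]
  if (motif$name == "FFL") {
    if (outd[p] == 2) return("input")
    if (ind[p] == 2) return("output")
    return("intermediate")
  }
  if (motif$name == "chain") {
    if (outd[p] == 1 && ind[p] == 0) return("source")
    if (ind[p] == 1 && outd[p] == 0) return("sink")
    return("middle")
  }
  if (motif$name == "v_out") {
    if (outd[p] == 2) return("regulator") else return("target")
  }
  if (motif$name == "v_in") {
    if (ind[p] == 2) return("target") else return("regulator")
  }
  if (motif$name == "cycle3") return("cycle")
  if (motif$name == "mutual_dyad") return("partner")
  paste0("orbit", positions[1] - 1)
}

#' Role partition of a motif (automorphism orbits)
#'
#' Two positions of a motif play the same role when some automorphism of the
#' motif maps one onto the other; the roles are therefore the automorphism
#' orbits of the motif digraph, computed here by exhaustive permutation check
#' (exact for motifs of up to four nodes).
#'
#' @param motif an [motif_class()].
#' @return an object of class `hm_roles`: list with `motif`, `orbits` (list of
#'   integer position vectors, ordered by their smallest position) and
#'   `labels` (character vector, one per orbit; known motifs get field names
#'   such as "input"/"intermediate"/"output").
#' @export
role_partition <- function(motif) {
  stopifnot(inherits(motif, "hm_motif"))
  A <- motif$adj
  k <- motif$size
  P <- all_perms(k)
  # automorphisms: p with A[p, p] == A
  autos <- P[vapply(seq_len(nrow(P)), function(r) {
    p <- P[r, ]
    all(A[p, p] == A)
  }, logical(1)), , drop = FALSE]
  # union-find over positions
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in seq_len(nrow(autos))) {
    for (i in seq_len(k)) {
      a <- find(i); b <- find(autos[r, i])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  orbits <- split(seq_len(k), roots)
  orbits <- orbits[order(vapply(orbits, min, integer(1)))]
  orbits <- unname(lapply(orbits, as.integer))
  labels <- vapply(orbits, function(o) orbit_label(motif, o), character(1))
  # disambiguate repeated labels (possible for unknown motifs)
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels, sep = "_")
  }
  structure(list(motif = motif, orbits = orbits, labels = labels),
            class = "hm_roles")
}

#' @export
print.hm_roles <- function(x, ...) {
  cat(sprintf("roles of '%s': %s\n", x$motif$name,
              paste(sprintf("%s{%s}", x$labels,
                            vapply(x$orbits, paste, character(1), collapse = ",")),
                    collapse = " ")))
  invisible(x)
}
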