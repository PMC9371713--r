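# Independent brute-force oracles used to validate the package's census and
# canonicalization machinery. These deliberately reimplement the operations
# from first principles (plain matrix permutation scans) rather than calling
# the package's own canonical machinery.

# all permutations of 1..k, one per row (small k only)
oracle_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) cbind(i, sub + (sub >= i))))
}

# serialize an adjacency matrix (diagonal ignored)
oracle_ser <- function(A) {
  diag(A) <- 0
  paste(A, collapse = "")
}

# the full isomorphism-orbit id of a small digraph: the sorted set of all
# permuted serializations (order-invariant by construction)
oracle_orbit_id <- function(A) {
  P <- oracle_perms(nrow(A))
  paste(sort(vapply(seq_len(nrow(P)), function(r) {
    p <- P[r, ]
    oracle_ser(A[p, p, drop = FALSE])
  }, character(1))), collapse = "|")
}

# 3-node adjacency from a 6-bit code, bits in the order
# (1->2),(2->1),(1->3),(3->1),(2->3),(3->2)
oracle_code_adj <- function(code) {
  A <- matrix(0L, 3, 3)
  pos <- list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  for (b in 1:6) {
    if (bitwAnd(code, bitwShiftL(1L, b - 1L)) != 0) {
      A[pos[[b]][1], pos[[b]][2]] <- 1L
    }
  }
  A
}

# weak connectivity of a <= 4 node digraph by reachability on the skeleton
oracle_connected <- function(A) {
  k <- nrow(A)
  sk <- (A + t(A)) > 0
  reach <- logical(k)
  reach[1] <- TRUE
  for (rep in seq_len(k)) {
    reach <- reach | apply(sk[, reach, drop = FALSE], 1, any)
  }
  all(reach)
}

# brute-force census of connected 3-node induced subgraphs: scan all triples,
# group by oracle orbit id; returns named count vector and instance lists
oracle_triad_census <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n)
  if (nrow(net$edges) > 0) {
    A[cbind(match(net$edges[, 1], net$nodes),
            match(net$edges[, 2], net$nodes))] <- 1L
  }
  diag(A) <- 0L
  counts <- integer(0)
  if (n < 3) return(counts)
  trips <- combn(n, 3)
  for (ci in seq_len(ncol(trips))) {
    s <- trips[, ci]
    sub <- A[s, s, drop = FALSE]
    if (!oracle_connected(sub)) next
    id <- oracle_orbit_id(sub)
    counts[id] <- if (is.na(counts[id])) 1L else counts[id] + 1L
  }
  counts[order(names(counts))]
}

# random small digraph as an hm_network (independent of the synthetic module)
oracle_random_net <- function(n, m, seed) {
  set.seed(seed)
  pairs <- which(matrix(TRUE, n, n) & !diag(n), arr.ind = TRUE)
  pick <- pairs[sample(nrow(pairs), m), , drop = FALSE]
  hm_network(cbind(sprintf("n%02d", pick[, 1]), sprintf("n%02d", pick[, 2])),
             nodes = sprintf("n%02d", seq_len(n)))
}

# in/out degree tables of a network, aligned over all nodes
degree_tables <- function(net) {
  list(out = table(factor(net$edges[, 1], levels = net$nodes)),
       inn = table(factor(net$edges[, 2], levels = net$nodes)))
}

# hand-rolled Benjamini-Hochberg step-up, for cross-checking q-values
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in seq(m, 1)) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# a synthetic trajectory object for classifier/synchronization unit tests
fake_trajectory <- function(time, ...) {
  states <- cbind(...)
  structure(list(time = time, states = states, model = NULL),
            class = "hm_trajectory")
}
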