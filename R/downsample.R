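# Neighborhood random-walk downsampling of a large network to an analyzable
# induced subnetwork. The walk mostly continues from the previous node and
# occasionally jumps back to the anchor's neighborhood; anchors are re-drawn
# at one-third checkpoints when too few unique nodes have been collected.

#' Downsample a network by a neighborhood random walk
#'
#' Samples a list `s` of `sz` nodes: the first is a random anchor `s0`, and
#' each subsequent entry is drawn uniformly from the neighborhood (union of
#' in- and out-neighbors) of the previous entry with probability
#' `p_continue`, otherwise from the neighborhood of the anchor. At one third
#' of the walk, if fewer than `floor(sz/3)/2` unique nodes have been
#' collected the anchor is re-drawn uniformly from the network; at two
#' thirds the same happens below `floor(sz/3)` unique nodes. The result is
#' the induced subgraph on the unique sampled nodes (every input edge among
#' them is retained).
#'
#' @param net an [hm_network()], non-empty.
#' @param sz walk length / target size (>= 3).
#' @param seed integer seed.
#' @param p_continue probability of continuing from the previous node
#'   (default 0.85).
#' @param max_retries retries for drawing an anchor with a non-empty
#'   neighborhood.
#' @return an [hm_network()] induced on the sampled nodes; the sampled walk
#'   is attached as attribute `"walk"`.
#' @export
downsample_network <- function(net, sz, seed, p_continue = 0.85,
                               max_retries = 100) {
  stopifnot(inherits(net, "hm_network"), sz >= 3, n_nodes(net) >= 1)
  set.seed(seed)
  idx <- edge_index(net)
  n <- n_nodes(net)
  nbr <- vector("list", n)
  for (r in seq_len(nrow(idx))) {
    a <- idx[r, 1]
    b <- idx[r, 2]
    if (a != b) {
      nbr[[a]] <- c(nbr[[a]], b)
      nbr[[b]] <- c(nbr[[b]], a)
    }
  }
  nbr <- lapply(nbr, function(x) sort(unique(x)))

  draw_anchor <- function() {
    for (t in seq_len(max_retries)) {
      cand <- sample.int(n, 1)
      if (length(nbr[[cand]]) > 0) return(cand)
    }
    stop("could not find an anchor with a non-empty neighborhood")
  }
  pick_from <- function(v) if (length(v) == 1) v else sample(v, 1)

  s0 <- draw_anchor()
  s <- s0
  third <- sz %/% 3
  step <- function(prev, anchor) {
    use_prev <- runif(1) < p_continue && length(nbr[[prev]]) > 0
    pool <- if (use_prev) nbr[[prev]] else nbr[[anchor]]
    pick_from(pool)
  }
  # first third (entries 2 .. third)
  for (i in seq_len(max(0, third - 1))) s <- c(s, step(s[length(s)], s0))
  if (length(unique(s)) < (third %/% 2)) s0 <- draw_anchor()
  # second third
  while (length(s) < 2 * third) s <- c(s, step(s[length(s)], s0))
  if (length(unique(s)) < third) s0 <- draw_anchor()
  # final third
  while (length(s) < sz) s <- c(s, step(s[length(s)], s0))

  keep <- sort(unique(s))
  labels <- net$nodes[keep]
  inside <- idx[, 1] %in% keep & idx[, 2] %in% keep
  sub_edges <- net$edges[inside, , drop = FALSE]
  out <- hm_network(sub_edges, nodes = labels)
  attr(out, "walk") <- net$nodes[s]
  out
}
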