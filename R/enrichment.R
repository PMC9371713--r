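# Detection of enriched motif combinations: role-overlap Jaccard statistics
# scored against an ensemble of randomized networks that preserve N, E, every
# node's in/out degree, the mutual-dyad count and the full census of
# connected three-node subgraphs.

#' Jaccard overlap of two node sets
#'
#' `|intersection| / |union|`. When both sets are empty the statistic is
#' undefined and `NA` is returned (such records are skipped with a flag by
#' the detection pipeline).
#'
#' @param set_i,set_j character vectors (duplicates ignored).
#' @return numeric in `[0, 1]`, or `NA` if both sets are empty.
#' @export
jaccard_overlap <- function(set_i, set_j) {
  set_i <- unique(set_i)
  set_j <- unique(set_j)
  u <- length(union(set_i, set_j))
  if (u == 0) return(NA_real_)
  length(intersect(set_i, set_j)) / u
}

#' Same-role repetition statistic
#'
#' The diagonal analogue of the Jaccard overlap: the fraction of nodes that
#' occupy a given motif role more than once, i.e. the number of nodes with
#' multiplicity > 1 divided by the number of distinct nodes in the role.
#'
#' @param role_multiset character vector of role occupants with repetitions.
#' @return numeric in `[0, 1]`, or `NA` for an empty role.
#' @export
same_role_repetition <- function(role_multiset) {
  if (length(role_multiset) == 0) return(NA_real_)
  tab <- table(role_multiset)
  sum(tab > 1) / length(tab)
}

#' Census-preserving network randomization
#'
#' Generates an ensemble of randomized networks each of which has the same
#' node count, edge count, per-node in/out degrees, mutual-dyad count and the
#' exact same counts of every connected three-node subgraph class as the
#' input. Each sample is produced by degree-preserving edge switching
#' followed by simulated annealing on the L1 distance between census count
#' vectors (Metropolis acceptance, geometric cooling), terminating at
#' distance zero. Sample i is driven by `seed + i` and the ensemble is fully
#' reproducible.
#'
#' @param net an [hm_network()].
#' @param max_k must be 3 (nulls preserving larger subgraph censuses are not
#'   feasible).
#' @param seed integer seed.
#' @param ensemble_size number of samples.
#' @param scramble_factor accepted switching swaps before annealing, as a
#'   multiple of the edge count.
#' @param max_retries per-sample retries (fresh sub-seed) when annealing
#'   fails to reach census distance zero within its iteration budget.
#' @param maxit annealing iteration budget per attempt.
#' @return list of [hm_network()] samples.
#' @export
randomize_preserving_census <- function(net, max_k = 3, seed = 1,
                                        ensemble_size = 100,
                                        scramble_factor = 5,
                                        max_retries = 5,
                                        maxit = 3e7) {
  if (max_k != 3) {
    stop("census-preserving randomization supports max_k = 3 only")
  }
  n <- n_nodes(net)
  idx <- edge_index(net)
  samples <- vector("list", ensemble_size)
  for (i in seq_len(ensemble_size)) {
    got <- NULL
    for (r in 0:max_retries) {
      sub_seed <- (seed + i + 7919L * r) %% .Machine$integer.max
      res <- cpp_rewire_census(n, idx, as.integer(sub_seed),
                               scramble_factor = as.integer(scramble_factor),
                               maxit = maxit)
      if (isTRUE(res$converged)) {
        got <- res
        break
      }
    }
    if (is.null(got)) {
      stop(sprintf(paste0(
        "annealing failed to restore the 3-node census for sample %d ",
        "after %d retries (last distance %.0f after %.0f iterations); ",
        "increase maxit or max_retries"),
        i, max_retries, res$energy, res$iterations))
    }
    samples[[i]] <- network_from_index(net$nodes, got$edges)
  }
  samples
}

#' Detect enriched motif combinations (hypermotifs)
#'
#' The full detection pipeline for one directed network:
#' 1. designate motif classes (by default, connected three-node classes with
#'    count Z-score > `z_threshold` against a degree-preserving switching
#'    null; or pass `class_keys` to override);
#' 2. assign the nodes participating in those motifs to role groups (one per
#'    automorphism orbit per class);
#' 3. compute the Jaccard overlap for every unordered pair of distinct roles,
#'    and the same-role repetition fraction for every role (diagonal);
#' 4. recompute the same statistics on an ensemble of census-preserving
#'    randomized networks;
#' 5. score each statistic with a Z-score against its null distribution,
#'    convert to a one-sided normal p-value in the direction of Z, apply
#'    Benjamini-Hochberg across all non-degenerate records jointly, and call
#'    a combination over- (Z > 0) or underrepresented (Z < 0) when q <
#'    `alpha`.
#'
#' @param net an [hm_network()].
#' @param n_random ensemble size for the census-preserving null.
#' @param alpha FDR threshold for calls.
#' @param seed integer seed driving every stochastic step.
#' @param class_keys canonical keys of motif classes to use; `NULL` for
#'   automatic designation.
#' @param z_threshold count Z-score cutoff for automatic motif designation.
#' @param n_random_motifs ensemble size for the motif-designation null
#'   (defaults to `n_random`).
#' @param ... passed to [randomize_preserving_census()].
#' @return data frame of class `hm_enrichment` with one row per tested role
#'   pair: `role_i`, `role_j`, `type` (`"pair"` or `"diagonal"`), `jaccard`,
#'   `null_mean`, `null_sd`, `z`, `p`, `q`, `call` (`"over"`, `"under"` or
#'   `"none"`) and `degenerate`. Attribute `"classes"` records the designated
#'   motif classes.
#' @export
detect_hypermotifs <- function(net, n_random = 100, alpha = 0.05, seed = 1,
                               class_keys = NULL, z_threshold = 2,
                               n_random_motifs = NULL, ...) {
  if (is.null(n_random_motifs)) n_random_motifs <- n_random
  if (n_random < 2) stop("need at least 2 null samples")
  if (is.null(class_keys)) {
    sig <- motif_significance(net, k = 3, n_random = n_random_motifs,
                              seed = seed)
    class_keys <- sig$key[sig$z > z_threshold & !sig$degenerate]
  }
  empty <- empty_enrichment(class_keys)
  if (length(class_keys) == 0) return(empty)

  roles <- role_table(net, class_keys = class_keys, k = 3)
  if (length(roles) == 0) return(empty)
  obs <- role_statistics(roles)
  if (nrow(obs$stats) == 0) return(empty)

  ensemble <- randomize_preserving_census(net, max_k = 3, seed = seed,
                                          ensemble_size = n_random, ...)
  null_mat <- vapply(ensemble, function(rnet) {
    rroles <- role_table(rnet, class_keys = class_keys, k = 3)
    match_statistics(obs$stats, rroles)
  }, numeric(nrow(obs$stats)))
  null_mat <- matrix(null_mat, nrow = nrow(obs$stats))

  null_mean <- rowMeans(null_mat, na.rm = TRUE)
  null_sd <- apply(null_mat, 1, sd, na.rm = TRUE)
  n_valid <- rowSums(!is.na(null_mat))
  if (any(n_valid < 2)) {
    stop("fewer than 2 valid ensemble samples for some role pairs")
  }
  degenerate <- !is.finite(null_sd) | null_sd == 0 | is.na(obs$stats$value)
  z <- ifelse(degenerate, 0, (obs$stats$value - null_mean) / null_sd)
  p <- ifelse(degenerate, NA_real_, pnorm(-abs(z)))
  q <- rep(NA_real_, length(p))
  q[!degenerate] <- p.adjust(p[!degenerate], method = "BH")
  call <- rep("none", length(z))
  hit <- !degenerate & !is.na(q) & q < alpha
  call[hit & z > 0] <- "over"
  call[hit & z < 0] <- "under"

  out <- data.frame(
    role_i = obs$stats$role_i,
    role_j = obs$stats$role_j,
    type = obs$stats$type,
    jaccard = obs$stats$value,
    null_mean = null_mean,
    null_sd = null_sd,
    z = z,
    p = p,
    q = q,
    call = call,
    degenerate = degenerate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("hm_enrichment", "data.frame")
  attr(out, "classes") <- class_keys
  out
}

empty_enrichment <- function(class_keys = character(0)) {
  out <- data.frame(
    role_i = character(0), role_j = character(0), type = character(0),
    jaccard = numeric(0), null_mean = numeric(0), null_sd = numeric(0),
    z = numeric(0), p = numeric(0), q = numeric(0), call = character(0),
    degenerate = logical(0), stringsAsFactors = FALSE
  )
  class(out) <- c("hm_enrichment", "data.frame")
  attr(out, "classes") <- class_keys
  out
}

# observed statistics: every unordered pair of distinct roles (Jaccard on
# deduplicated node sets) plus every diagonal (same-role repetition)
role_statistics <- function(roles) {
  ids <- vapply(roles, `[[`, character(1), "role_id")
  k <- length(roles)
  rows <- list()
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        rows[[length(rows) + 1]] <- data.frame(
          role_i = ids[i], role_j = ids[j], type = "pair",
          value = jaccard_overlap(roles[[i]]$node_set, roles[[j]]$node_set),
          stringsAsFactors = FALSE)
      }
    }
  }
  for (i in seq_len(k)) {
    rows[[length(rows) + 1]] <- data.frame(
      role_i = ids[i], role_j = ids[i], type = "diagonal",
      value = same_role_repetition(roles[[i]]$nodes),
      stringsAsFactors = FALSE)
  }
  stats <- do.call(rbind, rows)
  list(stats = stats, ids = ids)
}

# evaluate the observed statistic layout on another network's roles
match_statistics <- function(stats, roles) {
  ids <- vapply(roles, `[[`, character(1), "role_id")
  vapply(seq_len(nrow(stats)), function(r) {
    i <- match(stats$role_i[r], ids)
    j <- match(stats$role_j[r], ids)
    if (is.na(i) || is.na(j)) return(NA_real_)
    if (stats$type[r] == "diagonal") {
      same_role_repetition(roles[[i]]$nodes)
    } else {
      jaccard_overlap(roles[[i]]$node_set, roles[[j]]$node_set)
    }
  }, numeric(1))
}
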