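# Assignment of network nodes to motif role groups. A role group is one
# automorphism orbit of one motif class; the nodes occupying it (with
# multiplicity over instances) are the raw material of the combination
# enrichment statistics.

#' Assign network nodes to motif roles
#'
#' For one motif class and its enumerated occurrences, returns for every role
#' (automorphism orbit) the multiset of network nodes occupying it, with
#' multiplicity equal to the number of instances in which the node plays that
#' role, plus the deduplicated node set used by the Jaccard overlap
#' statistic.
#'
#' @param net an [hm_network()]; used to validate that each occurrence's
#'   induced subgraph realizes the motif.
#' @param instance_set one element of [enumerate_connected_subgraphs()]
#'   output: a list with `motif` and `instances`.
#' @return a list of role records, each with `motif` (name), `key` (class
#'   key), `orbit` (integer positions), `label`, `role_id`
#'   (`"<motif>.<label>"`), `nodes` (multiset, character vector with
#'   repetitions) and `node_set` (unique nodes).
#' @export
assign_roles <- function(net, instance_set) {
  motif <- instance_set$motif
  inst <- instance_set$instances
  stopifnot(inherits(motif, "hm_motif"), is.matrix(inst))
  # consistency: induced adjacency on each tuple, in position order, must
  # equal the motif representative (self-loops ignored)
  idx <- edge_index(net)
  n <- n_nodes(net)
  A <- matrix(0L, n, n)
  if (nrow(idx) > 0) A[idx] <- 1L
  diag(A) <- 0L
  for (r in seq_len(nrow(inst))) {
    tup <- match(inst[r, ], net$nodes)
    if (anyNA(tup) || !all(A[tup, tup] == motif$adj)) {
      stop("instance ", paste(inst[r, ], collapse = ","),
           " is not an induced occurrence of motif '", motif$name, "'")
    }
  }
  roles <- role_partition(motif)
  lapply(seq_along(roles$orbits), function(oi) {
    orbit <- roles$orbits[[oi]]
    nodes <- as.vector(inst[, orbit, drop = FALSE])
    list(
      motif = motif$name,
      key = motif$key,
      orbit = orbit,
      label = roles$labels[[oi]],
      role_id = paste0(motif$name, ".", roles$labels[[oi]]),
      nodes = nodes,
      node_set = sort(unique(nodes))
    )
  })
}

#' Role table for a set of motif classes
#'
#' Runs the census, keeps the requested classes and flattens their role
#' assignments into a single list of role records (see [assign_roles()]).
#'
#' @param net an [hm_network()].
#' @param class_keys canonical keys of the motif classes to keep; `NULL`
#'   keeps every class found.
#' @param k subgraph size (default 3).
#' @param validate check each instance against the motif (slower; the census
#'   output already satisfies this by construction).
#' @return list of role records.
#' @export
role_table <- function(net, class_keys = NULL, k = 3, validate = FALSE) {
  sub <- enumerate_connected_subgraphs(net, k)
  if (!is.null(class_keys)) sub <- sub[intersect(class_keys, names(sub))]
  out <- list()
  for (s in sub) {
    recs <- if (validate) {
      assign_roles(net, s)
    } else {
      roles_no_validate(s)
    }
    out <- c(out, recs)
  }
  out
}

roles_no_validate <- function(instance_set) {
  motif <- instance_set$motif
  inst <- instance_set$instances
  roles <- role_partition(motif)
  lapply(seq_along(roles$orbits), function(oi) {
    orbit <- roles$orbits[[oi]]
    nodes <- as.vector(inst[, orbit, drop = FALSE])
    list(
      motif = motif$name,
      key = motif$key,
      orbit = orbit,
      label = roles$labels[[oi]],
      role_id = paste0(motif$name, ".", roles$labels[[oi]]),
      nodes = nodes,
      node_set = sort(unique(nodes))
    )
  })
}

#' Export role assignments as a data frame
#'
#' @param roles list of role records from [assign_roles()] or [role_table()].
#' @return data frame with columns `motif`, `role`, `node`, `multiplicity`.
#' @export
role_data_frame <- function(roles) {
  rows <- lapply(roles, function(r) {
    tab <- table(r$nodes)
    data.frame(motif = r$motif, role = r$label,
               node = names(tab), multiplicity = as.integer(tab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
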