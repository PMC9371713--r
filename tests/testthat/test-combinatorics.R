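test_that("shared-node and linking-edge bounds follow the counting formulas", {
  expect_equal(max_shared_nodes(2, 2), 1)
  expect_equal(max_shared_nodes(3, 3), 2)
  expect_equal(max_shared_nodes(2, 3), 1)
  expect_error(max_shared_nodes(1, 3), "at least 2")

  expect_equal(max_linking_edges(3, 3, directed = TRUE), 18)
  expect_equal(max_linking_edges(2, 2, directed = FALSE), 4)
  expect_equal(max_linking_edges(2, 3, directed = TRUE), 12)

  expect_equal(count_interaction_topologies(2, 2, directed = FALSE), 16)
  expect_equal(count_interaction_topologies(2, 2, directed = TRUE), 256)
  expect_equal(count_interaction_topologies(1, 1, directed = TRUE), 4)
  expect_equal(count_interaction_topologies(3, 3, directed = TRUE), 2^18)
  expect_equal(count_interaction_topologies(2, 2, directed = TRUE,
                                            nonempty = TRUE), 255)
})

test_that("combination enumeration reproduces the known pattern counts", {
  ffl <- get_motif("FFL")
  dyad <- get_motif("mutual_dyad")
  ff <- enumerate_combinations(ffl, ffl)
  expect_length(ff, 12)
  expect_equal(as.vector(table(vapply(ff, `[[`, integer(1), "nv"))), c(6L, 6L))
  expect_length(enumerate_combinations(dyad, dyad), 1)
  expect_length(enumerate_combinations(dyad, ffl), 3)
})

test_that("emitted patterns contain both motifs as induced occurrences", {
  ffl <- get_motif("FFL")
  cyc <- get_motif("cycle3")
  for (pats in list(enumerate_combinations(ffl, ffl),
                    enumerate_combinations(cyc, ffl))) {
    keys <- vapply(pats, `[[`, character(1), "key")
    expect_false(anyDuplicated(keys) > 0)
    for (p in pats) {
      expect_equal(p$adj[p$nodes_a, p$nodes_a], p$motifA$adj,
                   ignore_attr = TRUE)
      expect_equal(p$adj[p$nodes_b, p$nodes_b], p$motifB$adj,
                   ignore_attr = TRUE)
    }
  }
})

test_that("enumeration is symmetric in the two motifs", {
  a <- get_motif("cycle3")
  b <- get_motif("FFL")
  k1 <- sort(vapply(enumerate_combinations(a, b), `[[`, character(1), "key"))
  k2 <- sort(vapply(enumerate_combinations(b, a), `[[`, character(1), "key"))
  expect_identical(k1, k2)
})

test_that("two three-node loops can still be joined along a shared edge", {
  cyc <- get_motif("cycle3")
  pats <- enumerate_combinations(cyc, cyc)
  expect_length(pats, 2)
  expect_setequal(vapply(pats, `[[`, integer(1), "nv"), c(1L, 2L))
})

test_that("the permissive merge convention keeps more patterns", {
  ffl <- get_motif("FFL")
  strict <- enumerate_combinations(ffl, ffl, strict = TRUE)
  loose <- enumerate_combinations(ffl, ffl, strict = FALSE)
  expect_gt(length(loose), length(strict))
  expect_gt(attr(strict, "excluded"), 0)
  expect_equal(attr(loose, "excluded"), 0)
})

test_that("extensions contain the core and match brute-force dedup", {
  dyad <- get_motif("mutual_dyad")
  pat <- enumerate_combinations(dyad, dyad)[[1]]
  exts <- enumerate_extensions(pat)
  # brute force: the two cross-edge subsets of {1->3, 3->1} on the chain of
  # mutual pairs give core, one added edge (two isomorphic variants), both
  expect_length(exts, 3)
  core_key <- canonical_form(pat$adj)
  expect_identical(canonical_form(exts[[1]]), core_key)
  for (e in exts) {
    expect_true(all(e[pat$adj == 1] == 1))
  }
})

test_that("interaction enumeration links disjoint motifs", {
  dyad <- get_motif("mutual_dyad")
  ints <- enumerate_interactions(dyad, dyad, max_edges = 1)
  # single directed link between two mutual dyads: all placements isomorphic
  expect_length(ints, 1)
  expect_equal(nrow(ints[[1]]$links), 1)
})
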