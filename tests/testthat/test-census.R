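test_that("single-motif graphs yield one class with one instance", {
  ffl <- read_edge_list(textConnection(c("X Y", "X Z", "Y Z")))
  sub <- enumerate_connected_subgraphs(ffl, 3)
  expect_length(sub, 1)
  expect_equal(sub[[1]]$motif$name, "FFL")
  expect_equal(nrow(sub[[1]]$instances), 1)

  cyc <- read_edge_list(textConnection(c("A B", "B C", "C A")))
  sub <- enumerate_connected_subgraphs(cyc, 3)
  expect_length(sub, 1)
  expect_equal(sub[[1]]$motif$name, "cycle3")
  expect_equal(nrow(sub[[1]]$instances), 1)
})

test_that("k larger than the network yields an empty result", {
  net <- read_edge_list(textConnection("A B"))
  expect_length(enumerate_connected_subgraphs(net, 3), 0)
})

test_that("census counts equal a brute-force triple scan on random graphs", {
  for (seed in 1:8) {
    net <- oracle_random_net(n = 15 + (seed %% 3) * 5, m = 60, seed = seed)
    counts <- triad_census_counts(net)
    oracle <- oracle_triad_census(net)
    expect_equal(unname(sort(as.integer(counts))),
                 unname(sort(as.integer(oracle))))
    expect_equal(sum(counts), sum(oracle))
    # class-resolved comparison via the instance sets
    sub <- enumerate_connected_subgraphs(net, 3)
    expect_equal(sum(vapply(sub, function(s) nrow(s$instances), integer(1))),
                 sum(oracle))
  }
})

test_that("instances are position-normalized induced occurrences", {
  net <- oracle_random_net(12, 40, 99)
  sub <- enumerate_connected_subgraphs(net, 3)
  for (s in sub) {
    # assign_roles validates induced-occurrence of every instance
    expect_no_error(assign_roles(net, s))
    # no duplicated occurrences
    key <- apply(apply(s$instances, 1, sort), 2, paste, collapse = ",")
    expect_false(anyDuplicated(key) > 0)
  }
})

test_that("two-node enumeration distinguishes single and mutual dyads", {
  net <- read_edge_list(textConnection(c("A B", "B A", "B C")))
  sub <- enumerate_connected_subgraphs(net, 2)
  names_found <- vapply(sub, function(s) s$motif$name, character(1))
  expect_true("mutual_dyad" %in% names_found)
  counts <- vapply(sub, function(s) nrow(s$instances), integer(1))
  expect_equal(sum(counts), 2)
})

test_that("degree-preserving rewiring keeps degrees, size and simplicity", {
  net <- oracle_random_net(30, 120, 7)
  for (seed in 1:5) {
    r <- rewire_degree_preserving(net, seed = seed)
    expect_identical(degree_tables(r), degree_tables(net))
    expect_equal(n_edges(r), n_edges(net))
    expect_false(any(r$edges[, 1] == r$edges[, 2]))
    expect_false(anyDuplicated(paste(r$edges[, 1], r$edges[, 2])) > 0)
  }
})

test_that("a fully constrained network is flagged degenerate", {
  ffl <- read_edge_list(textConnection(c("X Y", "X Z", "Y Z")))
  expect_warning(sig <- motif_significance(ffl, n_random = 5, seed = 1),
                 "constrain")
  expect_true(all(sig$degenerate))
  expect_true(all(sig$z == 0))
})

test_that("planted feedforward loops score high count Z-scores", {
  bg <- generate_background(80, 160, seed = 2)
  planted <- plant_patterns(bg, "FFL", copies = 30, seed = 3)
  sig <- motif_significance(planted$network, n_random = 30, seed = 4)
  ffl_row <- sig[sig$name == "FFL", ]
  expect_gt(ffl_row$z, 2)
  expect_gte(ffl_row$count, 30)
})
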