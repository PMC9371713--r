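test_that("the overlap statistics follow their definitions", {
  expect_equal(jaccard_overlap(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(jaccard_overlap(c("a", "b"), c("c", "d")), 0.0)
  expect_equal(jaccard_overlap(c("a", "b"), c("b", "c")), 1 / 3)
  expect_true(is.na(jaccard_overlap(character(0), character(0))))

  expect_equal(same_role_repetition(c("a", "b", "c")), 0.0)
  expect_equal(same_role_repetition(c("a", "a", "b", "b")), 1.0)
  expect_equal(same_role_repetition(c("a", "a", "b", "c")), 1 / 3)
  expect_true(is.na(same_role_repetition(character(0))))
})

test_that("Benjamini-Hochberg adjustment matches a hand-rolled step-up", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  expect_equal(p.adjust(p, method = "BH"), oracle_bh(p), tolerance = 1e-12)
  # q-values are monotone nondecreasing in p-rank
  q <- p.adjust(p, method = "BH")
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("census-preserving samples preserve all constrained quantities", {
  bg <- generate_background(40, 90, seed = 21)
  net <- plant_patterns(bg, "FFL", copies = 8, seed = 22)$network
  ens <- randomize_preserving_census(net, seed = 31, ensemble_size = 4)
  base_census <- triad_census_counts(net)
  for (r in ens) {
    expect_identical(triad_census_counts(r), base_census)
    expect_identical(degree_tables(r), degree_tables(net))
    expect_equal(n_edges(r), n_edges(net))
  }
  # samples are not copies of the original
  orig <- paste(net$edges[, 1], net$edges[, 2])
  hamming <- vapply(ens, function(r) {
    length(setdiff(paste(r$edges[, 1], r$edges[, 2]), orig))
  }, numeric(1))
  expect_true(all(hamming > 0))
})

test_that("the census-preserving ensemble is seed-reproducible", {
  bg <- generate_background(30, 70, seed = 5)
  e1 <- randomize_preserving_census(bg, seed = 8, ensemble_size = 2)
  e2 <- randomize_preserving_census(bg, seed = 8, ensemble_size = 2)
  expect_identical(e1, e2)
  e3 <- randomize_preserving_census(bg, seed = 9, ensemble_size = 2)
  expect_false(identical(e1, e3))
})

test_that("the detection pipeline is deterministic given a seed", {
  net <- synthetic_cascade_network(40, 80, 8, seed = 13)$network
  r1 <- detect_hypermotifs(net, n_random = 6, seed = 3,
                           class_keys = canonical_form(get_motif("FFL")$adj))
  r2 <- detect_hypermotifs(net, n_random = 6, seed = 3,
                           class_keys = canonical_form(get_motif("FFL")$adj))
  expect_identical(r1, r2)
})

test_that("records cover unordered pairs plus diagonals with valid calls", {
  net <- synthetic_cascade_network(40, 80, 10, seed = 17)$network
  rec <- detect_hypermotifs(net, n_random = 8, seed = 5,
                            class_keys = canonical_form(get_motif("FFL")$adj))
  k <- 3 # FFL roles
  expect_equal(sum(rec$type == "pair"), k * (k - 1) / 2)
  expect_equal(sum(rec$type == "diagonal"), k)
  expect_true(all(rec$call %in% c("over", "under", "none")))
  expect_true(all(rec$jaccard >= 0 & rec$jaccard <= 1, na.rm = TRUE))
  ok <- !rec$degenerate
  expect_true(all((rec$call[ok] != "none") == (rec$q[ok] < 0.05)))
  # q monotone in p-rank
  o <- order(rec$p[ok])
  expect_true(all(diff(rec$q[ok][o]) >= -1e-12))
})

test_that("detection on a motif-free background makes no calls", {
  bg <- generate_background(60, 90, seed = 41)
  rec <- detect_hypermotifs(bg, n_random = 6, seed = 41)
  expect_true(nrow(rec) == 0 || all(rec$call == "none"))
})

test_that("detection power increases with planting density", {
  key <- canonical_form(get_motif("FFL")$adj)
  z_at <- function(copies) {
    net <- synthetic_cascade_network(60, 120, copies, seed = 7)$network
    rec <- detect_hypermotifs(net, n_random = 10, seed = 7, class_keys = key)
    rec$z[rec$role_i == "FFL.output" & rec$role_j == "FFL.input"]
  }
  zs <- vapply(c(4, 12, 24), z_at, numeric(1))
  expect_true(all(diff(zs) > 0))
})
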