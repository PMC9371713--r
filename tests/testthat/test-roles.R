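ffl_net <- function(edges) read_edge_list(textConnection(edges))

test_that("roles of a single feedforward loop land on the right nodes", {
  net <- ffl_net(c("X Y", "X Z", "Y Z"))
  sub <- enumerate_connected_subgraphs(net, 3)
  roles <- assign_roles(net, sub[[1]])
  by_label <- setNames(roles, vapply(roles, `[[`, character(1), "label"))
  expect_equal(by_label$input$nodes, "X")
  expect_equal(by_label$intermediate$nodes, "Y")
  expect_equal(by_label$output$nodes, "Z")
})

test_that("a node shared between two loops appears in both role groups", {
  # Y is the output of the first loop and the input of the second
  net <- ffl_net(c("A B", "A Y", "B Y", "Y C", "Y D", "C D"))
  roles <- role_table(net, k = 3)
  by_label <- setNames(roles, vapply(roles, `[[`, character(1), "label"))
  expect_true("Y" %in% by_label$input$node_set)
  expect_true("Y" %in% by_label$output$node_set)
})

test_that("a cascade of chained loops matches hand enumeration", {
  # five FFLs chained output-to-input on nodes 1..11
  edges <- character(0)
  for (i in 0:4) {
    a <- paste0("n", 2 * i + 1)
    b <- paste0("n", 2 * i + 2)
    c <- paste0("n", 2 * i + 3)
    edges <- c(edges, paste(a, b), paste(a, c), paste(b, c))
  }
  net <- ffl_net(edges)
  sub <- enumerate_connected_subgraphs(net, 3)
  ffl <- sub[[which(vapply(sub, function(s) s$motif$name, character(1)) == "FFL")]]
  expect_equal(nrow(ffl$instances), 5)
  roles <- assign_roles(net, ffl)
  by_label <- setNames(roles, vapply(roles, `[[`, character(1), "label"))
  expect_setequal(by_label$input$nodes, paste0("n", c(1, 3, 5, 7, 9)))
  expect_setequal(by_label$output$nodes, paste0("n", c(3, 5, 7, 9, 11)))
  expect_setequal(by_label$intermediate$nodes, paste0("n", c(2, 4, 6, 8, 10)))
  # overlap between output and input roles is the chaining signature
  expect_setequal(intersect(by_label$input$node_set, by_label$output$node_set),
                  paste0("n", c(3, 5, 7, 9)))
})

test_that("the union of role sets is exactly the motif-participating nodes", {
  net <- oracle_random_net(20, 70, 5)
  sub <- enumerate_connected_subgraphs(net, 3)
  roles <- role_table(net, k = 3)
  nm <- sort(unique(unlist(lapply(sub, function(s) as.vector(s$instances)))))
  expect_setequal(sort(unique(unlist(lapply(roles, `[[`, "node_set")))), nm)
})

test_that("role assignment is invariant under node relabeling", {
  net <- oracle_random_net(12, 40, 11)
  perm <- sample(length(net$nodes))
  relab <- setNames(sprintf("q%02d", perm), net$nodes)
  net2 <- hm_network(cbind(relab[net$edges[, 1]], relab[net$edges[, 2]]),
                     nodes = unname(relab))
  r1 <- role_table(net, k = 3)
  r2 <- role_table(net2, k = 3)
  ids <- vapply(r1, `[[`, character(1), "role_id")
  ids2 <- vapply(r2, `[[`, character(1), "role_id")
  expect_setequal(ids, ids2)
  for (id in ids) {
    n1 <- sort(unname(relab[r1[[which(ids == id)]]$nodes]))
    n2 <- sort(r2[[which(ids2 == id)]]$nodes)
    expect_equal(n1, n2)
  }
})

test_that("inconsistent instances raise an error", {
  net <- ffl_net(c("X Y", "X Z", "Y Z"))
  sub <- enumerate_connected_subgraphs(net, 3)
  bad <- sub[[1]]
  bad$instances <- matrix(c("Y", "X", "Z"), nrow = 1)
  expect_error(assign_roles(net, bad), "not an induced occurrence")
})

test_that("role tables export as tidy data frames", {
  net <- ffl_net(c("X Y", "X Z", "Y Z"))
  df <- role_data_frame(role_table(net, k = 3))
  expect_named(df, c("motif", "role", "node", "multiplicity"))
  expect_equal(sum(df$multiplicity), 3)
})
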