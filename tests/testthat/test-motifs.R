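test_that("canonical keys are invariant under relabeling", {
  ffl1 <- rbind(c(0, 1, 1), c(0, 0, 1), c(0, 0, 0))
  p <- c(3, 1, 2)
  ffl2 <- ffl1[p, p]
  expect_identical(canonical_form(ffl1), canonical_form(ffl2))

  cyc <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_false(canonical_form(ffl1) == canonical_form(cyc))
})

test_that("all 64 labeled 3-node digraphs partition into the orbit classes", {
  pkg_keys <- character(64)
  oracle_ids <- character(64)
  for (code in 0:63) {
    A <- oracle_code_adj(code)
    pkg_keys[code + 1] <- canonical_form(A)
    oracle_ids[code + 1] <- oracle_orbit_id(A)
  }
  # same partition of the 64 labeled graphs into classes
  expect_identical(
    unname(split(0:63, pkg_keys))[order(vapply(split(0:63, pkg_keys), min, numeric(1)))],
    unname(split(0:63, oracle_ids))[order(vapply(split(0:63, oracle_ids), min, numeric(1)))]
  )
  # 16 classes in total, 13 of them connected
  expect_equal(length(unique(pkg_keys)), 16)
  conn <- vapply(0:63, function(code) oracle_connected(oracle_code_adj(code)),
                 logical(1))
  expect_equal(length(unique(pkg_keys[conn])), 13)
})

test_that("compiled canonical codes agree with the matrix-level keys", {
  codes <- hypermotifs:::cpp_canon_codes()
  for (code in 0:63) {
    canon <- codes[code + 1]
    # the canonical code represents the same isomorphism class ...
    expect_identical(canonical_form(oracle_code_adj(code)),
                     canonical_form(oracle_code_adj(canon)))
    # ... and is itself the canonical representative: its bit string in
    # pair-lexicographic order spells the canonical key
    bits <- as.integer(intToBits(canon)[1:6] != 0)
    expect_identical(canonical_form(oracle_code_adj(canon)),
                     paste0("k3:", paste(bits, collapse = "")))
  }
})

test_that("role partitions are the automorphism orbits", {
  ffl <- role_partition(get_motif("FFL"))
  expect_length(ffl$orbits, 3)
  expect_setequal(ffl$labels, c("input", "intermediate", "output"))

  cyc <- role_partition(get_motif("cycle3"))
  expect_length(cyc$orbits, 1)
  expect_equal(sort(cyc$orbits[[1]]), 1:3)

  dyad <- role_partition(get_motif("mutual_dyad"))
  expect_length(dyad$orbits, 1)

  vout <- role_partition(get_motif("v_out"))
  expect_length(vout$orbits, 2)
  expect_setequal(vout$labels, c("regulator", "target"))
  sizes <- sort(lengths(vout$orbits))
  expect_equal(sizes, c(1L, 2L))
})

test_that("orbits partition the position set for every built-in motif", {
  for (m in motif_library()) {
    rp <- role_partition(m)
    expect_setequal(unlist(rp$orbits), seq_len(m$size))
    expect_equal(sum(lengths(rp$orbits)), m$size)
  }
})
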