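test_that("match enumeration reproduces the printed diamine example", {
  q <- parse_smarts("CCN")
  d <- parse_smiles("NC1CCCCC1N")
  ms <- find_matches(q, d)
  expect_length(ms, 4L)
  expect_length(filter_mode(ms, "NON_IDENTICAL"), 4L)
  no <- filter_mode(ms, "NON_OVERLAPPING")
  expect_length(no, 2L)
  expect_length(intersect(no[[1]]$atom_set, no[[2]]$atom_set), 0L)
  eq <- equivalence_classes(d)
  ne <- filter_mode(ms, "NON_EQUIVALENT", eq)
  expect_length(ne, 2L)
  # number of admissible representative couples = product of class sizes
  keys <- vapply(ms, function(m)
    paste(sort(paste(seq_along(m$pairs), eq[m$pairs], sep = ">")), collapse = ","),
    character(1))
  expect_equal(prod(table(keys)), 4)
  expect_length(filter_mode(ms, "SINGLE"), 1L)
  expect_length(filter_mode(ms, "NON_IDENTICAL_FIRST"), 1L)
})

test_that("boolean match short-circuits existence", {
  expect_false(boolean_match(parse_smarts("CCN"), parse_smiles("C")))
  expect_true(boolean_match(parse_smarts("CCN"), parse_smiles("NC1CCCCC1N")))
  expect_true(boolean_match(parse_smarts("[R]"), parse_smiles("c1ccccc1")))
  expect_true(boolean_match(parse_smarts("[OH]"), parse_smiles("CCO")))
  expect_false(boolean_match(parse_smarts("[OH2]"), parse_smiles("CCO")))
})

test_that("component-level grouping constrains target components", {
  expect_gt(length(find_matches(parse_smarts("(C).(C)"), parse_smiles("CC.CC"))), 0L)
  expect_length(find_matches(parse_smarts("(C).(C)"), parse_smiles("CC")), 0L)
  expect_gt(length(find_matches(parse_smarts("(C.C)"), parse_smiles("CC"))), 0L)
  expect_length(find_matches(parse_smarts("(C.C)"), parse_smiles("C.C")), 0L)
  # ungrouped disconnected query is unconstrained
  expect_gt(length(find_matches(parse_smarts("C.C"), parse_smiles("CC"))), 0L)
})

test_that("match counts equal brute-force enumeration on small targets", {
  cases <- list(
    c("CCN", "NC1CCCCC1N"),
    c("CC", "CCC"),
    c("[OH]", "OCCO"),
    c("C=C", "C=CC=C"),
    c("c1ccccc1", "c1ccccc1"),
    c("[#6][#8]", "CC(O)CO"),
    c("[CX4]", "CC(C)(C)O"),
    c("[R]", "C1CC1C"))
  for (cs in cases) {
    q <- parse_smarts(cs[1]); t <- parse_smiles(cs[2])
    expect_equal(length(find_matches(q, t)), brute_force_match_count(q, t),
                 label = paste(cs[1], "on", cs[2]))
  }
})

test_that("filter outputs are subsets with the documented structure", {
  q <- parse_smarts("CC")
  t <- parse_smiles("CCCCCC")
  ms <- find_matches(q, t)
  eq <- equivalence_classes(t)
  for (mode in c("ALL", "SINGLE", "NON_OVERLAPPING", "NON_IDENTICAL",
                 "NON_EQUIVALENT", "NON_IDENTICAL_FIRST")) {
    out <- filter_mode(ms, mode, equivalence = eq)
    keys_in <- vapply(ms, function(m) paste(m$pairs, collapse = ","), character(1))
    keys_out <- vapply(out, function(m) paste(m$pairs, collapse = ","), character(1))
    expect_true(all(keys_out %in% keys_in), label = mode)
  }
  no <- filter_mode(ms, "NON_OVERLAPPING")
  cov <- unlist(lapply(no, function(m) m$atom_set))
  expect_false(anyDuplicated(cov) > 0)
  ne <- filter_mode(ms, "NON_EQUIVALENT", eq)
  keys <- vapply(ms, function(m)
    paste(sort(paste(seq_along(m$pairs), eq[m$pairs], sep = ">")), collapse = ","),
    character(1))
  expect_length(ne, length(unique(keys)))
})

test_that("matching is deterministic across repeated runs", {
  q <- parse_smarts("CCN")
  d <- parse_smiles("NC1CCCCC1N")
  a <- find_matches(q, d)
  b <- find_matches(q, d)
  expect_identical(a, b)
  pairs <- t(vapply(a, function(m) m$pairs, integer(3)))
  expect_identical(pairs, pairs[order(pairs[, 1], pairs[, 2], pairs[, 3]), ])
})

test_that("chirality primitives select the parity-consistent embedding", {
  lac <- parse_smiles("O[C@H](C)C(O)=O")
  hits_r <- find_matches(parse_smarts("[C@H](O)(C)C"), lac)
  hits_s <- find_matches(parse_smarts("[C@@H](O)(C)C"), lac)
  # both parities are representable by swapping the two carbon ligands,
  # but each written form admits exactly half of the 2 carbon assignments
  expect_equal(length(hits_r) + length(hits_s), 2L)
  expect_equal(length(hits_r), 1L)
  expect_equal(length(hits_s), 1L)
  expect_false(identical(hits_r[[1]]$pairs, hits_s[[1]]$pairs))
})
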