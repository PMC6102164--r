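codes_of <- function(rxn) sort(vapply(rxn$report$errors, function(e) e$code, character(1)))

test_that("SMIRKS parsing splits sides, pairs maps and counts unmapped atoms", {
  r <- parse_smirks("[NX3H0,NX3H1,NX3H2:1][CX3:2]=[OX1]>>[NX3H0,NX3H1,NX3H2:1][CX3:2]([H])[H]")
  expect_equal(r$pairs$map, c(1L, 2L))
  expect_length(r$unmapped_reactant, 1L)   # the carbonyl oxygen
  expect_length(r$unmapped_product, 2L)    # the two explicit H
  expect_length(r$report$errors, 0L)

  r2 <- parse_smirks("[N:1]1[C:2][C:3]=[C:4][C:5]1>>[N:1]1[C:2]=[C:3][C:4]=[C:5]1")
  expect_equal(nrow(r2$pairs), 5L)
  ups <- r2$plan$bond_order_updates
  expect_length(ups, 3L)
  expect_equal(vapply(ups, function(u) u$order, numeric(1)), c(2, 1, 2))

  r3 <- parse_smirks("C=C>[Pt]>CC")
  expect_equal(length(r3$agent$atoms), 1L)
  expect_error(parse_smirks("CC>CC"), "separator")
})

test_that("validation reports exactly the documented error classes", {
  expect_equal(codes_of(parse_smirks("[C:1][C:2]>>[C:1]=[C]")), "MISSING_MAP")
  expect_true("REPEATED_MAP" %in% codes_of(parse_smirks("[C:1][C:2]>>[C:1]=[C:1]")))
  expect_equal(codes_of(parse_smirks("[C:1][C:2]>>[N:1]=[C:2]")), "ELEMENT_MISMATCH")
  expect_equal(codes_of(parse_smirks("[C:1][C:2]>>[O:1][C:2]")), "ELEMENT_MISMATCH")
  expect_equal(codes_of(parse_smirks("[C:1]>>[C:1][Cl,Br]")),
               "UNMAPPED_PRODUCT_UNDEFINED_ELEMENT")
  expect_equal(codes_of(parse_smirks("[C:1]=[C:2]>>[C:1]-,=[C:2]")),
               "PRODUCT_BOND_ORDER_UNDEFINED")
  expect_equal(codes_of(parse_smirks("[C:1]>>[C:1]-,=C")),
               "PRODUCT_BOND_ORDER_UNDEFINED")
  # allowed cases
  expect_length(parse_smirks("[C:1][*:2]>>Cl[C:1][*:2]")$report$errors, 0L)
  expect_length(parse_smirks("[C:1][Cl,Br]>>[C:1]")$report$errors, 0L)
  expect_length(parse_smirks("[C:1]-,=[C:2]>>[C:1]-,=[C:2]")$report$errors, 0L)
  expect_length(parse_smirks("[C:1]-,=[C:2]>>[C:1]-[C:2]")$report$errors, 0L)
})

test_that("plan compilation derives atom, charge and bond instructions", {
  p <- parse_smirks("[C+,C++:1]>>[C:1]")$plan
  expect_length(p$charge_updates, 1L)
  expect_equal(p$charge_updates[[1]]$value, 0L)

  p2 <- parse_smirks("[C+,C++:1]>>[C+,C++:1][H]")$plan
  expect_length(p2$charge_updates, 0L)
  expect_length(p2$creations, 1L)
  expect_length(p2$bond_creations, 1L)

  p3 <- parse_smirks("C=C>>CC")$plan
  expect_length(p3$deletions, 2L)
  expect_length(p3$creations, 2L)
  expect_length(p3$bond_creations, 1L)

  # ambiguous mixed H expressions compile without an H update, with warning
  expect_warning(parse_smirks("[CH3,CH2:1]>>[CH2,CH1:1][OH]"), "H update")
  suppressWarnings(p4 <- parse_smirks("[CH3,CH2:1]>>[CH2,CH1:1][OH]")$plan)
  expect_length(p4$h_updates, 0L)
  p5 <- parse_smirks("[CH3:1]>>[CH2:1][OH]")$plan
  expect_length(p5$h_updates, 1L)
  expect_equal(p5$h_updates[[1]]$value, 2L)
})

test_that("fully mapped reactions have no atom deletions or creations", {
  for (s in c("[C:1]=[C:2]>>[C:1][C:2]",
              "[N:1]1[C:2][C:3]=[C:4][C:5]1>>[N:1]1[C:2]=[C:3][C:4]=[C:5]1",
              "[C:1][O:2]>>[C:1]=[O:2]")) {
    p <- parse_smirks(s)$plan
    expect_length(p$deletions, 0L)
    expect_length(p$creations, 0L)
  }
})

test_that("the reverse reaction compiles the inverse bond-order updates", {
  fw <- parse_smirks("[N:1]1[C:2][C:3]=[C:4][C:5]1>>[N:1]1[C:2]=[C:3][C:4]=[C:5]1")
  bw <- parse_smirks("[N:1]1[C:2]=[C:3][C:4]=[C:5]1>>[N:1]1[C:2][C:3]=[C:4][C:5]1")
  key <- function(p) {
    ups <- p$bond_order_updates
    sort(vapply(ups, function(u) sprintf("%d-%d", min(u$r1, u$r2), max(u$r1, u$r2)),
                character(1)))
  }
  expect_identical(key(fw$plan), key(bw$plan))
  ford <- vapply(fw$plan$bond_order_updates, function(u) u$order, numeric(1))
  bord <- vapply(bw$plan$bond_order_updates, function(u) u$order, numeric(1))
  expect_identical(sort(ford + bord), c(3, 3, 3))  # each update swaps 1 and 2
})

test_that("every valid fixture SMIRKS parses and every invalid one is rejected", {
  fx <- fixture_set()
  for (nm in names(fx$reactions)) {
    r <- suppressWarnings(parse_smirks(fx$reactions[[nm]]))
    expect_length(r$report$errors, 0L)
    expect_false(is.null(r$plan))
  }
  for (nm in names(fx$invalid_reactions)) {
    r <- suppressWarnings(parse_smirks(fx$invalid_reactions[[nm]]))
    expect_gt(length(r$report$errors), 0L)
  }
})
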