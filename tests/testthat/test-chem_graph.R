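test_that("SMILES parsing configures atoms, bonds and stereo", {
  m <- parse_smiles("C")
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$nH, 4L)
  expect_equal(nrow(m$bonds), 0L)

  d <- parse_smiles("NC1CCCCC1N")
  expect_equal(nrow(d$atoms), 8L)
  expect_equal(nrow(d$bonds), 8L)
  expect_length(d$stereo, 0L)

  l <- parse_smiles("O[C@H](C)C(O)=O")
  expect_length(l$stereo, 1L)
  expect_equal(l$stereo[[1]]$focus, 2L)
  expect_equal(l$stereo[[1]]$type, "tetrahedral")

  # charges, isotopes, multi-character elements
  q <- parse_smiles("C[N+](C)(C)C")
  expect_equal(q$atoms$charge[2], 1L)
  expect_equal(q$atoms$nH[2], 0L)
  i <- parse_smiles("[13CH4]")
  expect_equal(i$atoms$isotope, 13L)
  expect_equal(i$atoms$nH, 4L)
  expect_equal(parse_smiles("CCl")$atoms$element[2], "Cl")

  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("C(("), "branch|unbalanced")
})

test_that("implicit hydrogen counts follow the default-valence model", {
  expect_equal(parse_smiles("CC")$atoms$nH, c(3L, 3L))
  expect_equal(parse_smiles("N")$atoms$nH, 3L)
  expect_equal(parse_smiles("O=S(=O)(O)O")$atoms$nH[2], 0L)  # hypervalent S
  expect_equal(parse_smiles("[NH4+]")$atoms$nH, 4L)
  expect_equal(parse_smiles("[O-]C")$atoms$nH[1], 0L)
  # N with +1 charge and 4 single bonds gets 0 implicit H
  expect_equal(parse_smiles("C[N+](C)(C)C")$atoms$nH[2], 0L)
})

test_that("hydrogen conversions are mutually inverse and conserve H", {
  for (smi in c("CCO", "c1ccccc1", "CC(N)=O", "O[C@H](C)C(O)=O")) {
    m <- parse_smiles(smi)
    tot0 <- sum(smirkr:::mol_total_h(m))
    ex <- hydrogens(m, "implicit_to_explicit")
    expect_equal(sum(ex$atoms$element == "H"), tot0)
    expect_equal(sum(smirkr:::mol_total_h(ex)[ex$atoms$element != "H"]), tot0)
    back <- hydrogens(ex, "explicit_to_implicit")
    expect_identical(canon(back), canon(m))
  }
  # explicit conversion re-points tetrahedral placeholders to real atoms
  l <- hydrogens(parse_smiles("O[C@H](C)C(O)=O"), "implicit_to_explicit")
  expect_length(l$stereo, 1L)
  expect_false(any(l$stereo[[1]]$ligands == 0L))
})

test_that("aromaticity perception implements the Hueckel count and is idempotent", {
  b <- perceive_aromaticity(parse_smiles("C1=CC=CC=C1"))
  expect_equal(sum(b$atoms$aromatic), 6L)
  expect_equal(sum(b$bonds$aromatic), 6L)
  expect_equal(sum(parse_smiles("C1CCCCC1")$atoms$aromatic), 0L)
  py <- parse_smiles("C1=CC=CN1")
  expect_equal(sum(py$atoms$aromatic), 5L)
  # independent electron-count oracle on the pyrrole ring
  ri <- smirkr:::ring_info(parse_smiles("C1=CC=CN1"))
  expect_equal(huckel_ring_electrons(parse_smiles("C1=CC=CN1"), ri$rings[[1]]) %% 4, 2)
  # cyclobutadiene is 4n, quinone carbonyl carbons contribute 0
  expect_equal(sum(parse_smiles("C1=CC=C1")$atoms$aromatic), 0L)
  expect_equal(sum(parse_smiles("O=C1C=CC(=O)C=C1")$atoms$aromatic), 0L)
  # fused system and acyclic safety
  np <- parse_smiles("c1ccc2ccccc2c1")
  expect_equal(sum(np$atoms$aromatic), 10L)
  twice <- perceive_aromaticity(perceive_aromaticity(np))
  expect_identical(twice$atoms$aromatic, np$atoms$aromatic)
  expect_equal(sum(parse_smiles("C=CC=C")$atoms$aromatic), 0L)
})

test_that("SMILES round trips are stable including stereo parities", {
  fx <- fixture_set()$molecules
  for (smi in fx) {
    m <- parse_smiles(smi)
    s1 <- write_smiles(m, canonical = TRUE)
    m2 <- parse_smiles(s1)
    expect_identical(write_smiles(m2, canonical = TRUE), s1, label = smi)
    expect_equal(nrow(m2$atoms), nrow(m$atoms))
    expect_equal(length(m2$stereo), length(m$stereo), label = smi)
  }
})

test_that("the five spellings of (R)-2-hydroxypropanoic acid canonicalize identically", {
  sp <- c("O[C@H](C)C(O)=O", "O[C@@H](C(O)=O)C", "C[C@@H](O)C(O)=O",
          "C[C@H](C(O)=O)O", "C(O)(=O)[C@H](O)C")
  cs <- vapply(sp, function(s) canon(parse_smiles(s)), character(1))
  expect_length(unique(cs), 1L)
  # the enantiomer canonicalizes differently
  expect_false(canon(parse_smiles("O[C@@H](C)C(O)=O")) %in% cs)
})

test_that("connected components partition the graph and carry stereo", {
  cc <- connected_components(parse_smiles("CC.C"))
  expect_length(cc, 2L)
  expect_equal(sort(vapply(cc, function(m) nrow(m$atoms), integer(1))), c(1L, 2L))
  expect_length(connected_components(parse_smiles("CC")), 1L)
  mixed <- parse_smiles("O[C@H](C)C(O)=O.CC")
  parts <- connected_components(mixed)
  nstereo <- vapply(parts, function(m) length(m$stereo), integer(1))
  expect_equal(sort(nstereo), c(0L, 1L))
})

test_that("equivalence classes agree with brute-force automorphism orbits", {
  for (smi in c("c1ccccc1", "NC1CCCCC1N", "CCO", "CC(C)C", "C1=CC=CN1",
                "CC(N)=O", "F/C=C/F")) {
    m <- parse_smiles(smi)
    expect_identical(equivalence_classes(m), brute_force_orbits(m), label = smi)
  }
  # 3-ethylpyridine: no two ring atoms equivalent
  eq <- equivalence_classes(parse_smiles("CCc1cccnc1"))
  expect_equal(length(unique(eq)), length(eq))
})

test_that("cis and trans double bonds survive parsing and canonical writing", {
  tr <- parse_smiles("F/C=C/F")
  ci <- parse_smiles("F/C=C\\F")
  expect_equal(tr$stereo[[1]]$config, "opposite")
  expect_equal(ci$stereo[[1]]$config, "together")
  expect_false(canon(tr) == canon(ci))
  tr2 <- parse_smiles(canon(tr))
  expect_equal(tr2$stereo[[1]]$config, "opposite")
  # branch-form spelling of the cis isomer
  expect_identical(canon(parse_smiles("C(/F)=C/F")), canon(ci))
})
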