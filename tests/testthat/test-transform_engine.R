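proc_cfg <- function(...) transform_config(process_result_structures = TRUE, ...)

test_that("mapped and unmapped double-bond reduction differ by fragmentation", {
  mapped <- parse_smirks("[C:1]=[C:2]>>[C:1][C:2]")
  unmapped <- parse_smirks("C=C>>CC")
  mixed <- parse_smirks("[C:1]=C>>[C:1]C")

  pr <- apply_in_place(mapped, parse_smiles("C=CC"), proc_cfg())
  expect_true(pr$modified)
  expect_length(connected_components(pr$molecule), 1L)
  expect_identical(canon(post_process(pr$molecule, proc_cfg())), canon(parse_smiles("CCC")))

  un <- apply_in_place(unmapped, parse_smiles("C=CC"), transform_config())
  frags <- lapply(connected_components(un$molecule), post_process, proc_cfg())
  expect_length(frags, 2L)
  expect_setequal(vapply(frags, canon, character(1)),
                  c(canon(parse_smiles("C")), canon(parse_smiles("CC"))))

  cy <- apply_in_place(unmapped, parse_smiles("C1=CCCCC1"), transform_config())
  expect_length(connected_components(cy$molecule), 2L)
  cym <- apply_in_place(mapped, parse_smiles("C1=CCCCC1"), proc_cfg())
  expect_length(connected_components(cym$molecule), 1L)
  expect_identical(canon(post_process(cym$molecule, proc_cfg())),
                   canon(parse_smiles("C1CCCCC1")))

  mx <- apply_in_place(mixed, parse_smiles("C=CC"), transform_config())
  expect_length(connected_components(mx$molecule), 2L)

  # no site: unchanged and not modified
  none <- apply_in_place(mapped, parse_smiles("CCC"), transform_config())
  expect_false(none$modified)
  expect_identical(canon(none$molecule), canon(parse_smiles("CCC")))
})

test_that("aromatic hydroxylation yields four distinct pyridinol products", {
  ep <- hydrogens(parse_smiles("CCc1cccnc1"), "implicit_to_explicit")
  rh <- parse_smirks("[c:1][H]>>[c:1]O[H]")
  res <- apply_with_copies(rh, ep, transform_config())
  expect_length(res$products, 4L)
  cs <- vapply(res$products, function(p) canon(hydrogens(p, "explicit_to_implicit")),
               character(1))
  expect_length(unique(cs), 4L)
})

test_that("ring aromatization plus post-processing produces aromatic pyrrole", {
  ra <- parse_smirks("[N:1]1[C:2][C:3]=[C:4][C:5]1>>[N:1]1[C:2]=[C:3][C:4]=[C:5]1")
  res <- apply_with_copies(ra, parse_smiles("N1CC=CC1"), proc_cfg())
  expect_length(res$products, 1L)
  p <- res$products[[1]]
  expect_equal(sum(p$atoms$aromatic), 5L)
  expect_identical(canon(p), canon(parse_smiles("c1cc[nH]c1")))
  # without post-processing the Kekule product is returned unchanged
  res2 <- apply_with_copies(ra, parse_smiles("N1CC=CC1"), transform_config())
  expect_equal(sum(res2$products[[1]]$atoms$aromatic), 0L)
})

test_that("implicit H transformation drives methyl hydroxylation", {
  rim <- parse_smirks("[CH3:1]>>[CH2:1][OH]")
  cfg <- transform_config(h_atoms_transformation = TRUE)
  res <- apply_with_copies(rim, parse_smiles("CCC"), cfg)
  expect_length(res$products, 2L)
  cs <- vapply(res$products, canon, character(1))
  expect_length(unique(cs), 1L)
  expect_identical(unique(cs), canon(parse_smiles("CCCO")))
  # equivalent sites collapse to one representative
  cfg2 <- transform_config(h_atoms_transformation = TRUE,
                           filter_equivalent_mappings = TRUE)
  expect_length(apply_with_copies(rim, parse_smiles("CCC"), cfg2)$products, 1L)
  # with the flag off, the H primitives only matched (stale counts remain)
  res3 <- apply_with_copies(rim, parse_smiles("CCC"), transform_config())
  expect_equal(res3$products[[1]]$atoms$nH[res3$sites[[1]]$pairs[1]], 3L)
})

test_that("explicit-H descriptions of hydroxylation are equivalent", {
  pol <- hydrogens(parse_smiles("C=CO"), "implicit_to_explicit")
  va <- parse_smirks("[C:1]=[C:2][O:3][H]>>[C:1][C:2][O:3][H]")
  vb <- parse_smirks("[C:1]=[C:2][O:3][H:4]>>[C:1][C:2][O:3][H:4]")
  pa <- apply_with_copies(va, pol, transform_config())$products[[1]]
  pb <- apply_with_copies(vb, pol, transform_config())$products[[1]]
  expect_identical(canon(pa), canon(pb))
  # hydroxylation inserted between C and H on explicit-H ethane
  eth <- hydrogens(parse_smiles("CC"), "implicit_to_explicit")
  rv <- parse_smirks("[CH3:1][H:2]>>[C:1]O[H:2]")
  out <- apply_with_copies(rv, eth, transform_config())
  expect_gt(length(out$products), 0L)
  expect_identical(canon(hydrogens(out$products[[1]], "explicit_to_implicit")),
                   canon(parse_smiles("CCO")))
})

test_that("amide reduction edits the graph as mapped", {
  r <- parse_smirks("[NX3H0,NX3H1,NX3H2:1][CX3:2]=[OX1]>>[NX3H0,NX3H1,NX3H2:1][CX3:2]([H])[H]")
  nma <- hydrogens(parse_smiles("CC(=O)NC"), "implicit_to_explicit")
  res <- apply_with_copies(r, nma, transform_config())
  expect_length(res$products, 1L)
  p <- hydrogens(res$products[[1]], "explicit_to_implicit")
  expect_identical(canon(p), canon(parse_smiles("CCNC")))
})

test_that("externally supplied sites are re-verified and applied", {
  ep <- hydrogens(parse_smiles("CCc1cccnc1"), "implicit_to_explicit")
  rh <- parse_smirks("[c:1][H]>>[c:1]O[H]")
  all_sites <- find_matches(rh$reactant, ep)
  one <- apply_at_sites(rh, ep, all_sites[1], transform_config())
  expect_length(one$products, 1L)
  expect_true(one$applied)
  none <- apply_at_sites(rh, ep, list(), transform_config())
  expect_false(none$applied)
  expect_length(none$products, 0L)
  stale <- all_sites[[1]]
  stale$pairs[2] <- 1L  # no longer an H atom
  expect_message(res <- apply_at_sites(rh, ep, list(stale), transform_config()),
                 "rejected")
  expect_false(res$applied)
  expect_equal(res$rejected, 1L)
})

test_that("stereo elements not touched by the site are always preserved", {
  lac <- parse_smiles("O[C@H](C)C(O)=O")
  ester <- parse_smirks("[C:1](=[O:2])[OX2H1:3]>>[C:1](=[O:2])[OX2H0:3]C")
  for (flag in c(TRUE, FALSE)) {
    cfg <- transform_config(apply_stereo_transformation = flag)
    out <- apply_with_copies(ester, lac, cfg)
    expect_length(out$products[[1]]$stereo, 1L)
    expect_equal(out$products[[1]]$stereo[[1]]$parity, lac$stereo[[1]]$parity)
  }
})

test_that("ligand replacement re-points or removes the stereo element by flag", {
  lac <- parse_smiles("O[C@H](C)C(O)=O")
  rb <- parse_smirks("[C:1][OX2H1]>>[C:1]N")
  # site on the stereocentre is enumerated first
  with_flag <- apply_with_copies(rb, lac, transform_config(apply_stereo_transformation = TRUE))
  expect_length(with_flag$products[[1]]$stereo, 1L)
  expect_identical(canon(with_flag$products[[1]]), canon(parse_smiles("N[C@H](C)C(O)=O")))
  without <- apply_with_copies(rb, lac, transform_config())
  expect_length(without$products[[1]]$stereo, 0L)
})

test_that("SMIRKS-defined parity inversion flips the centre", {
  lac <- parse_smiles("O[C@H](C)C(O)=O")
  rf <- parse_smirks("[C@H:1]([O:2])([C:3])[C:4]>>[C@@H:1]([O:2])([C:3])[C:4]")
  out <- apply_with_copies(rf, lac, transform_config(apply_stereo_transformation = TRUE))
  expect_length(out$products, 1L)
  expect_identical(canon(out$products[[1]]), canon(parse_smiles("O[C@@H](C)C(O)=O")))
})

test_that("duplicate-equivalent ligands invalidate a stereo centre", {
  lac <- parse_smiles("O[C@H](C)C(O)=O")
  rd <- parse_smirks("[C:1][OX2H1]>>[C:1]C")  # OH -> methyl beside existing methyl
  out <- apply_with_copies(rd, lac, transform_config(apply_stereo_transformation = TRUE))
  expect_length(out$products[[1]]$stereo, 0L)
})

test_that("heavy-atom count changes by creations minus deletions per site", {
  cases <- list(
    list("C=C>>CC", "C=CC", 0L),
    list("[C:1][Cl]>>[C:1]", "CCCl", -1L),
    list("[C:1]>>[C:1]O", "CC", 1L),
    list("[CH3:1]>>[CH2:1][OH]", "CC", 1L))
  for (cs in cases) {
    rxn <- parse_smirks(cs[[1]])
    target <- parse_smiles(cs[[2]])
    res <- apply_with_copies(rxn, target, transform_config(ss_mode = "SINGLE"))
    dn <- nrow(res$products[[1]]$atoms) - nrow(target$atoms)
    expect_equal(dn, cs[[3]], label = cs[[1]])
  }
})

test_that("reverse application at the same site restores the molecule", {
  cases <- list(
    c("[C:1]=[C:2]>>[C:1][C:2]", "C=CC"),
    c("[N:1]1[C:2][C:3]=[C:4][C:5]1>>[N:1]1[C:2]=[C:3][C:4]=[C:5]1", "N1CC=CC1"),
    c("[C:1][O:2]>>[C:1]=[O:2]", "CCO"))
  for (cs in cases) {
    fw <- parse_smirks(cs[1])
    parts <- strsplit(cs[1], ">>", fixed = TRUE)[[1]]
    bw <- parse_smirks(paste0(parts[2], ">>", parts[1]))
    m0 <- parse_smiles(cs[2])
    site <- find_matches(fw$reactant, m0)[[1]]
    m1 <- execute_plan_at_site(fw$plan, m0, site, transform_config())
    m2 <- execute_plan_at_site(bw$plan, m1, site, transform_config())
    expect_identical(canon(m2), canon(m0), label = cs[1])
  }
})

test_that("in-place application is deterministic and mode-consistent", {
  rim <- parse_smirks("[CH3:1]>>[CH2:1][OH]")
  cfg <- transform_config(h_atoms_transformation = TRUE, ss_mode = "SINGLE")
  t1 <- apply_in_place(rim, parse_smiles("CCC"), cfg)$molecule
  t2 <- apply_in_place(rim, parse_smiles("CCC"), cfg)$molecule
  expect_identical(canon(t1), canon(t2))
  all_prod <- apply_with_copies(rim, parse_smiles("CCC"),
                                transform_config(h_atoms_transformation = TRUE,
                                                 ss_mode = "ALL"))
  expect_true(canon(t1) %in% vapply(all_prod$products, canon, character(1)))
})

test_that("post-processing honours each flag", {
  stale <- parse_smiles("CCO")
  stale$atoms$nH <- c(0L, 0L, 0L)
  fixed <- post_process(stale, transform_config(process_result_structures = TRUE))
  expect_equal(fixed$atoms$nH, c(3L, 2L, 1L))
  # all-clear config returns the product unchanged
  noop <- post_process(stale, transform_config(
    process_result_structures = TRUE, clear_hybridization_before = FALSE,
    clear_aromaticity_before = FALSE, clear_implicit_h_before = FALSE,
    check_aromaticity_on_process = FALSE))
  expect_identical(noop$atoms$nH, stale$atoms$nH)
  expect_identical(post_process(stale, transform_config())$atoms$nH, stale$atoms$nH)
  # added implicit hydrogens can be converted to explicit atoms
  conv <- post_process(parse_smiles("CC"), transform_config(
    process_result_structures = TRUE, add_implicit_h_on_process = TRUE,
    convert_added_implicit_to_explicit = TRUE))
  expect_equal(sum(conv$atoms$element == "H"), 6L)
})
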