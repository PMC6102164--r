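ae <- function(s) parse_smarts(s)$atoms[[1]]

test_that("expression matching modes follow the printed semantics", {
  expect_true(expression_match(ae("[Cl,F,Br]"), ae("[Cl,F,Br]"), "EXACT"))
  expect_true(expression_match(ae("[Br,Cl,F]"), ae("[Cl,F,Br]"), "EXACT"))
  expect_false(expression_match(ae("[Cl,F,Br]"), ae("[Cl,F]"), "EXACT"))
  expect_true(expression_match(ae("[Cl,F,Br]"), ae("[Cl,F,Br,I]"), "SPECIFIC_MATCHES_GENERIC"))
  expect_true(expression_match(ae("[Cl,F,Br]"), ae("*"), "SPECIFIC_MATCHES_GENERIC"))
  expect_false(expression_match(ae("[Cl,F,Br]"), ae("[Cl,F]"), "SPECIFIC_MATCHES_GENERIC"))
  # reverse inclusion
  expect_true(expression_match(ae("[Cl,F,Br]"), ae("[Cl,F]"), "GENERIC_MATCHES_SPECIFIC"))
  expect_false(expression_match(ae("[Cl,F,Br]"), ae("[Cl,F,Br,I]"), "GENERIC_MATCHES_SPECIFIC"))
  # recursion is undecidable outside EXACT
  expect_warning(v <- expression_match(ae("[$(CO)]"), ae("*"), "SPECIFIC_MATCHES_GENERIC"))
  expect_true(is.na(v))
  expect_true(expression_match(ae("[$(CO)]"), ae("[$(CO)]"), "EXACT"))
})

test_that("inclusion modes are dual and EXACT implies both", {
  corpus <- c("[Cl,F,Br]", "[Cl,F]", "*", "[C]", "[c]", "[#6]", "[C,N]",
              "[CH3]", "[CH3,CH2]", "[N+]", "[!C]", "[C;R]", "[CX4]", "[OX2H1]")
  for (a in corpus) for (b in corpus) {
    smg <- expression_match(ae(a), ae(b), "SPECIFIC_MATCHES_GENERIC")
    gms <- expression_match(ae(b), ae(a), "GENERIC_MATCHES_SPECIFIC")
    expect_identical(smg, gms, label = paste(a, b))
  }
  for (a in corpus) {
    expect_true(expression_match(ae(a), ae(a), "EXACT"))
    expect_true(expression_match(ae(a), ae(a), "SPECIFIC_MATCHES_GENERIC"))
    expect_true(expression_match(ae(a), ae(a), "GENERIC_MATCHES_SPECIFIC"))
  }
})

test_that("inclusion agrees with direct set comparison over the finite universe", {
  corpus <- c("[Cl,F,Br]", "[C,N]", "[CH3]", "[!C]", "[C]", "*", "[N+]")
  uni <- smirkr:::atom_universe(lapply(corpus, ae))
  sat <- function(e) {
    vapply(seq_len(nrow(uni)), function(i) smirkr:::eval_on_record(e, uni[i, ]),
           logical(1))
  }
  sets <- lapply(corpus, function(s) sat(ae(s)))
  for (i in seq_along(corpus)) for (j in seq_along(corpus)) {
    expected <- all(!sets[[i]] | sets[[j]])
    got <- expression_match(ae(corpus[i]), ae(corpus[j]), "SPECIFIC_MATCHES_GENERIC")
    expect_identical(got, expected, label = paste(corpus[i], corpus[j]))
  }
})

test_that("query-against-query isomorphism respects the expression mode", {
  q1 <- parse_smarts("C[Cl,F]")
  q2 <- parse_smarts("C[Cl,F,Br]")
  expect_length(query_isomorphism(q1, q2, "SPECIFIC_MATCHES_GENERIC"), 1L)
  expect_length(query_isomorphism(q2, q1, "SPECIFIC_MATCHES_GENERIC"), 0L)
  expect_gte(length(query_isomorphism(q1, q1, "EXACT")), 1L)
  expect_gte(length(query_isomorphism(parse_smarts("CC"), parse_smarts("CCC"),
                                      "SPECIFIC_MATCHES_GENERIC")), 1L)
})

test_that("generic-versus-concrete search checks both reaction sides", {
  # ketone reduction: both sides match their molecules
  red <- parse_smirks("[CX3]=[OX1]>>[CX4][OX2H1]")
  acetone <- parse_smiles("CC(C)=O")
  isoprop <- parse_smiles("CC(C)O")
  aceticacid <- parse_smiles("CC(O)=O")
  expect_true(search_concrete(red, concrete_reaction(list(acetone), list(isoprop))))
  expect_false(search_concrete(red, concrete_reaction(list(acetone), list(aceticacid))))
  # a reactant-side failure is decisive
  expect_false(search_concrete(red, concrete_reaction(list(parse_smiles("CC")),
                                                      list(isoprop))))
  # multi-component sides may reuse molecules unless grouped apart
  two <- parse_smirks("C.C>>CC")
  expect_true(search_concrete(two, concrete_reaction(list(parse_smiles("CC")),
                                                     list(parse_smiles("CCC")))))
  grouped <- parse_smirks("(C).(C)>>CC")
  expect_false(search_concrete(grouped, concrete_reaction(list(parse_smiles("CC")),
                                                          list(parse_smiles("CCC")))))
  expect_true(search_concrete(grouped,
    concrete_reaction(list(parse_smiles("CC"), parse_smiles("CC")),
                      list(parse_smiles("CCC")))))
})

test_that("concrete reaction identity is multiset identity of canonical forms", {
  ra <- concrete_reaction(list(parse_smiles("CCO"), parse_smiles("CC")),
                          list(parse_smiles("C=C")))
  rb <- concrete_reaction(list(parse_smiles("CC"), parse_smiles("OCC")),
                          list(parse_smiles("C=C")))
  rc <- concrete_reaction(list(parse_smiles("CC")), list(parse_smiles("C=C")))
  expect_true(reaction_identity(ra, rb))
  expect_false(reaction_identity(ra, rc))
  # stereo-equivalent spellings compare equal
  rs1 <- concrete_reaction(list(parse_smiles("O[C@H](C)C(O)=O")), list(parse_smiles("CC")))
  rs2 <- concrete_reaction(list(parse_smiles("C[C@@H](O)C(O)=O")), list(parse_smiles("CC")))
  rs3 <- concrete_reaction(list(parse_smiles("O[C@@H](C)C(O)=O")), list(parse_smiles("CC")))
  expect_true(reaction_identity(rs1, rs2))
  expect_false(reaction_identity(rs1, rs3))
})
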