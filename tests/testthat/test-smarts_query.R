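test_that("SMARTS parsing builds expression trees with correct precedence", {
  q <- parse_smarts("CCN")
  expect_equal(length(q$atoms), 3L)
  expect_equal(nrow(q$bonds), 2L)
  expect_true(all(vapply(q$bexprs, function(e) e$prim == "default", logical(1))))

  q2 <- parse_smarts("[CH3;!$(C*=O);!$(C*N)]")
  expect_equal(length(q2$atoms), 1L)
  e <- q2$atoms[[1]]
  expect_equal(e$op, "andlo")
  expect_length(e$args, 3L)
  negs <- Filter(function(a) a$op == "not", e$args)
  expect_length(negs, 2L)
  expect_true(all(vapply(negs, function(a)
    expression_mentions(a, "recursive"), logical(1))))

  q3 <- parse_smarts("([#6]).([#8])")
  expect_equal(q3$comp, c(1L, 2L))

  expect_error(parse_smarts("[C"), "unbalanced")
  expect_error(parse_smarts("[12C]"), "isotope")
  expect_error(parse_smarts("[Qq]"), "unknown")
})

test_that("atom expression evaluation follows SMARTS leaf semantics", {
  ae <- function(s) parse_smarts(s)$atoms[[1]]
  expect_true(eval_atom_expression(ae("[Cl,F,Br]"), parse_smiles("CCl"), 2L))
  expect_true(eval_atom_expression(ae("[!C;!N]"), parse_smiles("CO"), 2L))
  # recursive veto on the methyl of acetone
  expect_false(eval_atom_expression(ae("[CH3;!$(C*=O)]"), parse_smiles("CC(C)=O"), 1L))
  expect_true(eval_atom_expression(ae("[CH3;!$(C*=O)]"), parse_smiles("CCC"), 1L))
  # connectivity, degree, ring, valence
  bz <- parse_smiles("c1ccccc1")
  expect_true(eval_atom_expression(ae("[cX3]"), bz, 1L))
  expect_true(eval_atom_expression(ae("[R1]"), bz, 1L))
  expect_false(eval_atom_expression(ae("[R2]"), bz, 1L))
  expect_true(eval_atom_expression(ae("[r6]"), bz, 1L))
  eth <- parse_smiles("CCO")
  expect_true(eval_atom_expression(ae("[CD1]"), eth, 1L))
  expect_false(eval_atom_expression(ae("[CD1]"), eth, 2L))
  expect_true(eval_atom_expression(ae("[v2]"), eth, 3L))
  expect_true(eval_atom_expression(ae("[OH1]"), eth, 3L))
  # aromatic versus aliphatic element forms
  expect_true(eval_atom_expression(ae("[c]"), bz, 1L))
  expect_false(eval_atom_expression(ae("[C]"), bz, 1L))
  expect_true(eval_atom_expression(ae("[#6]"), bz, 1L))
})

test_that("bond expression evaluation distinguishes pure and aromatic orders", {
  pr <- parse_smiles("C=CC")
  k <- smirkr:::mol_bond_between(pr, 1L, 2L)
  be <- function(s) parse_smarts(s)$bexprs[[1]]
  expect_true(eval_bond_expression(be("C=C"), pr, k))
  expect_true(eval_bond_expression(be("C~C"), pr, k))
  expect_false(eval_bond_expression(be("C-C"), pr, k))
  bz <- parse_smiles("c1ccccc1")
  # an aromatic bond is neither pure single nor pure double
  expect_false(eval_bond_expression(be("C-,=C"), bz, 1L))
  expect_true(eval_bond_expression(be("C:C"), bz, 1L))
  expect_true(eval_bond_expression(be("C@C"), bz, 1L))
  # default bond: single or aromatic
  expect_true(eval_bond_expression(be("CC"), bz, 1L))
  expect_false(eval_bond_expression(be("CC"), pr, k))
})

test_that("element and property extraction reports only unique values", {
  ae <- function(s) parse_smarts(s)$atoms[[1]]
  expect_true(is.na(extract_element(ae("[Cl,Br,I]"))))
  expect_true(is.na(extract_element(ae("[!C;!N]"))))
  expect_true(is.na(extract_element(ae("[CH3,NH2,OH]"))))
  expect_equal(extract_element(ae("[CH3,CH2,CH;!$(CO)]")), "C")
  expect_equal(extract_element(ae("[C:1]")), "C")
  p <- extract_properties(ae("[C+]"))
  expect_equal(p$element, "C")
  expect_equal(p$charge, 1L)
  expect_true(is.na(extract_properties(ae("[C+,C++]"))$charge))
  p2 <- extract_properties(ae("[CH2:1]"))
  expect_equal(p2$total_H, 2L)
  expect_equal(p2$element, "C")
})

test_that("normalized unparsing is parse-stable and order-insensitive", {
  for (s in c("CCN", "[CH3;!$(C*=O);!$(C*N)]", "([#6]).([#8])", "[C;R:3]",
              "c1ccccc1", "C(F)(Cl)Br", "[O-,OH]", "C/C=C/C", "[NX3H0,NX3H1,NX3H2:1]")) {
    u <- unparse_smarts(parse_smarts(s))
    expect_identical(unparse_smarts(parse_smarts(u)), u, label = s)
  }
  # structurally identical expressions normalize identically
  n1 <- smirkr:::normalize_expression(parse_smarts("[Br,Cl,F]")$atoms[[1]])
  n2 <- smirkr:::normalize_expression(parse_smarts("[F,Cl,Br]")$atoms[[1]])
  expect_identical(n1, n2)
})

test_that("recursive evaluation terminates and nests", {
  q <- parse_smarts("[$(C[$(CO)])]")  # nested recursion
  expect_true(eval_atom_expression(q$atoms[[1]], parse_smiles("CCO"), 1L))
  deep <- parse_smarts("[CH3;!$(C*=O);!$(C*N)]")
  m <- parse_smiles("CCCC")
  expect_true(eval_atom_expression(deep$atoms[[1]], m, 1L))
})
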