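## SMARTS logical expressions
##
## An expression is a tree of nodes:
##   list(op = "leaf", prim = <name>, value = ..., arom = ...)
##   list(op = "not", arg = node)
##   list(op = "and", args = list(...))     # high-precedence & (or juxtaposition)
##   list(op = "or", args = list(...))      # ,
##   list(op = "andlo", args = list(...))   # ;
## with SMARTS precedence ! > & > , > ;.
##
## Atom primitives: any (*), aliphatic (A), aromatic (a), element (value =
## symbol, arom = TRUE/FALSE/NA for lowercase/uppercase/#n), charge, totalH
## (H), implH (h), connectivity (X), degree (D), ring_count (R, value NA =
## any ring), ring_size (r), valence (v), recursive ($(...), value = parsed
## query_molecule), chiral (@ = +1, @@ = -1).
## Bond primitives: single, double, triple, aromatic, any (~), ring (@),
## dirup (/), dirdown (\), default (unwritten bond: single-or-aromatic).

leaf <- function(prim, value = NULL, arom = NULL) {
  list(op = "leaf", prim = prim, value = value, arom = arom)
}

expr_not <- function(arg) list(op = "not", arg = arg)
expr_join <- function(op, args) {
  if (length(args) == 1L) args[[1]] else list(op = op, args = args)
}

## Evaluation context for one target molecule, precomputed once per search.
match_context <- function(mol) {
  ri <- ring_info(mol)
  n <- n_atoms(mol)
  bmat <- matrix(0L, n, n)
  for (k in seq_len(n_bonds(mol))) {
    bmat[mol$bonds$a1[k], mol$bonds$a2[k]] <- k
    bmat[mol$bonds$a2[k], mol$bonds$a1[k]] <- k
  }
  list(mol = mol, deg = mol_degree(mol), expl_h = mol_explicit_h(mol),
       bos = mol_bond_order_sum(mol), ring = ri,
       comp = component_ids(mol), bmat = bmat)
}

#' Evaluate a SMARTS atom expression on an atom
#'
#' Leaf semantics follow the SMARTS standard; a recursive leaf is true iff
#' its sub-pattern has at least one match rooted so that its first atom maps
#' to the candidate atom. Chirality primitives are evaluated only when a
#' complete `mapping` is supplied (during candidate screening they are
#' neutral), because a parity comparison needs the full neighbour
#' correspondence.
#'
#' @param expr an atom expression (from [parse_smarts]).
#' @param mol the target [molecule].
#' @param ai target atom index.
#' @param ctx optional precomputed context (internal).
#' @param mapping,qmol,qi full-match context for chirality (internal).
#' @return `TRUE` or `FALSE`.
#' @export
eval_atom_expression <- function(expr, mol, ai, ctx = NULL,
                                 mapping = NULL, qmol = NULL, qi = NULL) {
  if (is.null(ctx)) ctx <- match_context(mol)
  eval_aexpr(expr, ctx, ai, mapping, qmol, qi)
}

eval_aexpr <- function(e, ctx, ai, mapping = NULL, qmol = NULL, qi = NULL) {
  switch(e$op,
    leaf = eval_atom_leaf(e, ctx, ai, mapping, qmol, qi),
    not = !eval_aexpr(e$arg, ctx, ai, mapping, qmol, qi),
    and = , andlo = all(vapply(e$args, eval_aexpr, logical(1), ctx, ai, mapping, qmol, qi)),
    or = any(vapply(e$args, eval_aexpr, logical(1), ctx, ai, mapping, qmol, qi)),
    stop("bad expression node"))
}

eval_atom_leaf <- function(e, ctx, ai, mapping, qmol, qi) {
  at <- ctx$mol$atoms
  switch(e$prim,
    any = TRUE,
    aliphatic = !at$aromatic[ai],
    aromatic = at$aromatic[ai],
    element = {
      if (at$element[ai] != e$value) return(FALSE)
      if (is.na(e$arom)) TRUE else at$aromatic[ai] == e$arom
    },
    charge = at$charge[ai] == e$value,
    totalH = (at$nH[ai] + ctx$expl_h[ai]) == e$value,
    implH = at$nH[ai] == e$value,
    connectivity = (ctx$deg[ai] + at$nH[ai]) == e$value,
    degree = ctx$deg[ai] == e$value,
    ring_count = if (is.na(e$value)) ctx$ring$count[ai] > 0L
                 else ctx$ring$count[ai] == e$value,
    ring_size = e$value %in% ctx$ring$sizes[[ai]],
    valence = (ctx$bos[ai] + at$nH[ai]) == e$value,
    recursive = recursive_match(e$value, ctx, ai),
    chiral = eval_chiral_leaf(e, ctx, ai, mapping, qmol, qi),
    stop("unknown atom primitive: ", e$prim))
}

recursive_match <- function(sub_qmol, ctx, ai) {
  boolean_match(sub_qmol, ctx$mol, root = ai, ctx = ctx)
}

## Chirality: neutral while the mapping is incomplete; with a full mapping,
## compare the permutation parity of the query's written neighbour order
## (mapped onto target atoms) with the target stereo element.
eval_chiral_leaf <- function(e, ctx, ai, mapping, qmol, qi) {
  if (is.null(mapping)) return(TRUE)
  se <- stereo_on_atom(ctx$mol, ai)
  if (is.null(se) || se$type != "tetrahedral") return(FALSE)
  qlig <- query_ligand_order(qmol, qi)
  if (length(qlig) != 4L) return(TRUE)
  tlig <- vapply(qlig, function(q) if (q == 0L) 0L else mapping[q], integer(1))
  # a query implicit-H placeholder stands for whatever single ligand of the
  # target stereo element is not otherwise accounted for
  miss <- setdiff(se$ligands, tlig)
  if (sum(tlig == 0L) == 1L && length(miss) == 1L) tlig[tlig == 0L] <- miss
  if (!setequal(tlig, se$ligands)) return(TRUE)
  (e$value * perm_sign(tlig, se$ligands)) == se$parity
}

## Written neighbour order of a query atom, with a 0 placeholder for an
## implicit hydrogen (inserted after the parent) when the expression pins
## total H to exactly one and the atom has only three written neighbours.
query_ligand_order <- function(qmol, qi) {
  lig <- qmol$neigh[[qi]]
  if (length(lig) == 3L) {
    th <- extract_properties(qmol$atoms[[qi]])$total_H
    if (!is.na(th) && th == 1L) {
      at <- if (length(lig) && lig[1] < qi && lig[1] > 0L) 2L else 1L
      lig <- append(lig, 0L, after = at - 1L)
    }
  }
  lig
}

#' Evaluate a SMARTS bond expression on a bond
#'
#' The default (unwritten) bond matches a single or an aromatic bond;
#' `-` matches a pure single bond (not aromatic), `=` a pure double bond,
#' `#` triple, `:` aromatic, `~` anything, `@` a ring bond, and the
#' directional primitives `/` and `\` match single bonds (direction is used
#' for stereo description, not for matching).
#'
#' @param expr a bond expression.
#' @param mol the target [molecule].
#' @param bi bond index in `mol$bonds`.
#' @param ctx optional precomputed context (internal).
#' @return `TRUE` or `FALSE`.
#' @export
eval_bond_expression <- function(expr, mol, bi, ctx = NULL) {
  if (is.null(ctx)) ctx <- match_context(mol)
  eval_bexpr(expr, ctx, bi)
}

eval_bexpr <- function(e, ctx, bi) {
  switch(e$op,
    leaf = eval_bond_leaf(e, ctx, bi),
    not = !eval_bexpr(e$arg, ctx, bi),
    and = , andlo = all(vapply(e$args, eval_bexpr, logical(1), ctx, bi)),
    or = any(vapply(e$args, eval_bexpr, logical(1), ctx, bi)),
    stop("bad expression node"))
}

eval_bond_leaf <- function(e, ctx, bi) {
  b <- ctx$mol$bonds
  switch(e$prim,
    single = b$order[bi] == 1L && !b$aromatic[bi],
    double = b$order[bi] == 2L && !b$aromatic[bi],
    triple = b$order[bi] == 3L,
    aromatic = b$aromatic[bi],
    any = TRUE,
    ring = ctx$ring$ring_bond[bi],
    dirup = , dirdown = b$order[bi] == 1L && !b$aromatic[bi],
    default = (b$order[bi] == 1L && !b$aromatic[bi]) || b$aromatic[bi],
    stop("unknown bond primitive: ", e$prim))
}

## --- property extraction --------------------------------------------------

## Set of values a property can take under satisfying assignments; NULL is
## "anything" (TOP). NOT is conservatively TOP.
possible_set <- function(e, getter) {
  switch(e$op,
    leaf = getter(e),
    not = NULL,
    and = , andlo = {
      sets <- lapply(e$args, possible_set, getter)
      sets <- Filter(Negate(is.null), sets)
      if (!length(sets)) NULL else Reduce(intersect, sets)
    },
    or = {
      sets <- lapply(e$args, possible_set, getter)
      if (any(vapply(sets, is.null, logical(1)))) NULL
      else unique(unlist(sets))
    })
}

unique_or_na <- function(set, na) {
  if (is.null(set) || length(set) != 1L) na else set[[1]]
}

#' Extract the element implied by an atom expression
#'
#' Returns the unique element symbol that every satisfying assignment of the
#' expression must have, or `NA` when the element is undefined (for example
#' `[Cl,Br,I]` or `[!C;!N]`). Used by SMIRKS validation to reject creation of
#' atoms with unknown element.
#'
#' @param expr an atom expression.
#' @return Element symbol or `NA_character_`.
#' @export
extract_element <- function(expr) {
  unique_or_na(possible_set(expr, function(l)
    if (l$prim == "element") l$value else NULL), NA_character_)
}

#' Extract uniquely determined atom properties from an expression
#'
#' Reports `element`, `charge`, `total_H` and `aromatic` when each is the
#' same under every satisfying assignment, `NA` otherwise. Drives
#' charge/hydrogen change detection when compiling a SMIRKS transformation.
#'
#' @param expr an atom expression.
#' @return A list with `element`, `charge`, `total_H`, `aromatic`.
#' @export
extract_properties <- function(expr) {
  list(
    element = extract_element(expr),
    charge = unique_or_na(possible_set(expr, function(l)
      if (l$prim == "charge") l$value else NULL), NA_integer_),
    total_H = unique_or_na(possible_set(expr, function(l)
      if (l$prim == "totalH") l$value else NULL), NA_integer_),
    aromatic = unique_or_na(possible_set(expr, function(l) {
      if (l$prim == "element" && !is.null(l$arom) && !is.na(l$arom)) return(l$arom)
      if (l$prim == "aromatic") return(TRUE)
      if (l$prim == "aliphatic") return(FALSE)
      NULL
    }), NA))
}

## Unique bond order implied by a bond expression: 1, 2, 3, "ar", or NA when
## undefined. The default bond creates a single bond (its matching semantics
## stay single-or-aromatic).
extract_bond_order <- function(expr) {
  set <- possible_set(expr, function(l)
    switch(l$prim,
      single = , dirup = , dirdown = , default = 1,
      double = 2, triple = 3, aromatic = "ar", NULL))
  v <- unique_or_na(set, NA)
  if (is.null(v)) NA else v
}

## Chirality primitive carried by an expression (top-level conjunctions
## only): +1, -1 or 0 when absent.
extract_chirality <- function(e) {
  switch(e$op,
    leaf = if (e$prim == "chiral") e$value else 0L,
    not = 0L,
    and = , andlo = {
      vals <- vapply(e$args, extract_chirality, integer(1))
      vals <- vals[vals != 0L]
      if (length(vals)) vals[1] else 0L
    },
    or = 0L)
}

## --- normalization --------------------------------------------------------

## Canonical string form of an expression; primitives are sorted by a fixed
## key within each operator level so that textually different but
## structurally identical expressions compare equal (EXACT search mode).
normalize_expression <- function(e, kind = c("atom", "bond")) {
  kind <- match.arg(kind)
  norm <- function(e) {
    switch(e$op,
      leaf = leaf_token(e, kind),
      not = paste0("!", wrap(norm(e$arg), e$arg, 1L)),
      and = join(e$args, "&", 2L),
      or = join(e$args, ",", 3L),
      andlo = join(e$args, ";", 4L))
  }
  lvl <- function(e) switch(e$op, leaf = 0L, not = 1L, and = 2L, or = 3L, andlo = 4L)
  wrap <- function(s, e, maxlvl) s   # precedence already unambiguous in tokens
  join <- function(args, sep, l) {
    parts <- vapply(args, norm, character(1))
    paste(sort(parts), collapse = sep)
  }
  norm(e)
}

leaf_token <- function(e, kind) {
  if (kind == "bond") {
    return(switch(e$prim, single = "-", double = "=", triple = "#",
                  aromatic = ":", any = "~", ring = "@", dirup = "/",
                  dirdown = "\\", default = ""))
  }
  switch(e$prim,
    any = "*",
    aliphatic = "A",
    aromatic = "a",
    element = {
      if (is.na(e$arom)) paste0("#", atomic_number(e$value))
      else if (e$arom) tolower(e$value)
      else e$value
    },
    charge = if (e$value >= 0) paste0("+", e$value) else paste0("-", abs(e$value)),
    totalH = paste0("H", e$value),
    implH = paste0("h", e$value),
    connectivity = paste0("X", e$value),
    degree = paste0("D", e$value),
    ring_count = if (is.na(e$value)) "R" else paste0("R", e$value),
    ring_size = paste0("r", e$value),
    valence = paste0("v", e$value),
    chiral = if (e$value > 0) "@" else "@@",
    recursive = paste0("$(", unparse_smarts(e$value), ")"))
}

element_symbols <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V",
  "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br",
  "Kr", "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag",
  "Cd", "In", "Sn", "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr",
  "Nd", "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi")

atomic_number <- function(sym) {
  z <- match(sym, element_symbols)
  if (is.na(z)) stop("unknown element symbol: ", sym)
  z
}
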