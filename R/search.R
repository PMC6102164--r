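#' Match one SMARTS expression against another
#'
#' Expression-versus-expression comparison for generic-reaction search.
#' `EXACT` compares normalized forms. `SPECIFIC_MATCHES_GENERIC` holds when
#' every assignment satisfying the query also satisfies the target (the
#' query's satisfying set is included in the target's);
#' `GENERIC_MATCHES_SPECIFIC` is the reverse inclusion. Inclusions are
#' decided by brute force over a finite universe of atom (or bond)
#' descriptions covering the supported primitives; expressions containing
#' recursive sub-patterns are undecidable here and return `NA` with a
#' warning (treated as non-match by [query_isomorphism]).
#'
#' @param query,target two atom expressions or two bond expressions.
#' @param mode `"EXACT"`, `"SPECIFIC_MATCHES_GENERIC"` or
#'   `"GENERIC_MATCHES_SPECIFIC"`.
#' @param kind `"atom"` or `"bond"`.
#' @return `TRUE`, `FALSE`, or `NA` when undecidable.
#' @export
#' @examples
#' a <- parse_smarts("[Cl,F,Br]")$atoms[[1]]
#' b <- parse_smarts("[Cl,F,Br,I]")$atoms[[1]]
#' expression_match(a, b, "SPECIFIC_MATCHES_GENERIC")  # TRUE
#' expression_match(a, b, "EXACT")                     # FALSE
expression_match <- function(query, target,
                             mode = c("EXACT", "SPECIFIC_MATCHES_GENERIC",
                                      "GENERIC_MATCHES_SPECIFIC"),
                             kind = c("atom", "bond")) {
  mode <- match.arg(mode)
  kind <- match.arg(kind)
  if (mode == "EXACT")
    return(identical(normalize_expression(query, kind),
                     normalize_expression(target, kind)))
  if (has_recursion(query) || has_recursion(target)) {
    warning("recursive expression: inclusion mode undecided", call. = FALSE)
    return(NA)
  }
  if (mode == "GENERIC_MATCHES_SPECIFIC")
    return(expression_match(target, query, "SPECIFIC_MATCHES_GENERIC", kind))
  uni <- if (kind == "atom") atom_universe(list(query, target))
         else bond_universe()
  evalu <- if (kind == "atom") eval_on_record else eval_bond_record
  for (i in seq_len(nrow(uni))) {
    if (evalu(query, uni[i, ]) && !evalu(target, uni[i, ])) return(FALSE)
  }
  TRUE
}

has_recursion <- function(e) expression_mentions(e, "recursive")

## Finite universe of abstract atom descriptions. Dimensions referenced by
## neither expression are pinned to a default to keep enumeration small.
atom_universe <- function(exprs) {
  mention <- function(p) any(vapply(exprs, expression_mentions, logical(1), p))
  grid <- expand.grid(
    element = c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I"),
    charge = -2:2,
    totalH = 0:4,
    aromatic = c(FALSE, TRUE),
    degree = if (mention("degree") || mention("connectivity")) 0:4 else 2L,
    ring_count = if (mention("ring_count")) 0:2 else 1L,
    ring_size = if (mention("ring_size")) c(0L, 5L, 6L) else 0L,
    valence = if (mention("valence")) 0:6 else 4L,
    implH_extra = if (mention("implH")) 0:1 else 0L,
    chiral = if (mention("chiral")) c(0L, 1L, -1L) else 0L,
    stringsAsFactors = FALSE)
  grid
}

## Evaluate an expression on one abstract atom record.
eval_on_record <- function(e, rec) {
  switch(e$op,
    leaf = eval_leaf_record(e, rec),
    not = !eval_on_record(e$arg, rec),
    and = , andlo = all(vapply(e$args, eval_on_record, logical(1), rec)),
    or = any(vapply(e$args, eval_on_record, logical(1), rec)))
}

eval_leaf_record <- function(e, rec) {
  switch(e$prim,
    any = TRUE,
    aliphatic = !rec$aromatic,
    aromatic = rec$aromatic,
    element = rec$element == e$value &&
      (is.na(e$arom) || rec$aromatic == e$arom),
    charge = rec$charge == e$value,
    totalH = rec$totalH == e$value,
    implH = max(rec$totalH - rec$implH_extra, 0L) == e$value,
    connectivity = (rec$degree + rec$totalH) == e$value,
    degree = rec$degree == e$value,
    ring_count = if (is.na(e$value)) rec$ring_count > 0L else rec$ring_count == e$value,
    ring_size = rec$ring_size == e$value,
    valence = rec$valence == e$value,
    chiral = rec$chiral == e$value,
    stop("unexpected primitive in universe evaluation: ", e$prim))
}

bond_universe <- function() {
  expand.grid(order = c("1", "2", "3", "ar"), ring = c(FALSE, TRUE),
              stringsAsFactors = FALSE)
}

eval_bond_record <- function(e, rec) {
  switch(e$op,
    leaf = switch(e$prim,
      single = rec$order == "1",
      double = rec$order == "2",
      triple = rec$order == "3",
      aromatic = rec$order == "ar",
      any = TRUE,
      ring = rec$ring,
      dirup = , dirdown = rec$order == "1",
      default = rec$order %in% c("1", "ar")),
    not = !eval_bond_record(e$arg, rec),
    and = , andlo = all(vapply(e$args, eval_bond_record, logical(1), rec)),
    or = any(vapply(e$args, eval_bond_record, logical(1), rec)))
}

#' Subgraph isomorphism between two query molecules
#'
#' Matches one SMARTS pattern against another: atom and bond compatibility
#' is [expression_match] under the chosen mode. Used for searching a query
#' SMIRKS against a database of generic (SMIRKS-encoded) reactions.
#'
#' @param query,target [query_molecule][parse_smarts] objects.
#' @param mode as in [expression_match].
#' @return A list of matches (`pairs`: query atom to target atom indices).
#' @export
query_isomorphism <- function(query, target, mode = "SPECIFIC_MATCHES_GENERIC") {
  nq <- n_query_atoms(query)
  nt <- n_query_atoms(target)
  if (nq == 0L || nt == 0L) return(list())
  qadj <- query_adjacency(query)
  tadj <- query_adjacency(target)
  order_q <- query_order(query, qadj)
  qb <- function(a, b) query_bond_index(query, a, b)
  tb <- function(a, b) query_bond_index(target, a, b)
  atom_ok <- matrix(NA, nq, nt)
  bond_cache <- new.env(parent = emptyenv())
  results <- list()
  mapping <- rep(NA_integer_, nq)
  used <- logical(nt)
  compat_atom <- function(qi, ti) {
    if (is.na(atom_ok[qi, ti])) {
      v <- expression_match(query$atoms[[qi]], target$atoms[[ti]], mode, "atom")
      atom_ok[qi, ti] <<- isTRUE(v)
    }
    atom_ok[qi, ti]
  }
  compat_bond <- function(qk, tk) {
    key <- paste(qk, tk)
    v <- bond_cache[[key]]
    if (is.null(v)) {
      v <- isTRUE(expression_match(query$bexprs[[qk]], target$bexprs[[tk]], mode, "bond"))
      bond_cache[[key]] <- v
    }
    v
  }
  recurse <- function(pos) {
    if (pos > nq) {
      results[[length(results) + 1L]] <<-
        list(pairs = mapping, atom_set = sort(unique(mapping)))
      return(invisible(NULL))
    }
    qi <- order_q[pos]
    for (t in seq_len(nt)) {
      if (used[t]) next
      if (!compat_atom(qi, t)) next
      ok <- TRUE
      for (nb in qadj[[qi]]) {
        if (is.na(mapping[nb])) next
        tk <- tb(t, mapping[nb])
        if (is.na(tk) || !compat_bond(qb(qi, nb), tk)) { ok <- FALSE; break }
      }
      if (!ok) next
      mapping[qi] <<- t; used[t] <<- TRUE
      recurse(pos + 1L)
      mapping[qi] <<- NA_integer_; used[t] <<- FALSE
    }
  }
  suppressWarnings(recurse(1L))
  sort_matches(results)
}

#' Concrete reactions
#'
#' A concrete (ordinary) reaction: explicit reactant and product molecules,
#' optionally agents. The counterpart of a generic [parse_smirks] rule.
#'
#' @param reactants,products non-empty lists of [molecule] objects.
#' @param agents optional list of molecules.
#' @return An object of class `concrete_reaction`.
#' @export
concrete_reaction <- function(reactants, products, agents = list()) {
  stopifnot(length(reactants) > 0L, length(products) > 0L)
  structure(list(reactants = reactants, products = products, agents = agents),
            class = "concrete_reaction")
}

#' Search a generic SMIRKS against a concrete reaction
#'
#' True iff every connected component of the reactant-side query matches
#' some target reactant molecule and every product-side component matches
#' some target product (several components may match the same molecule;
#' component-level groups constrain co-location as in substructure search).
#'
#' @param query a [parse_smirks] reaction.
#' @param target a [concrete_reaction].
#' @return `TRUE` or `FALSE`.
#' @export
search_concrete <- function(query, target) {
  side_ok <- function(qside, mols) {
    comps <- query_components(qside)
    if (!length(comps)) return(TRUE)
    assign_ok <- function(ci, grp_mol) {
      if (ci > length(comps)) return(TRUE)
      comp <- comps[[ci]]
      grp <- comp$group
      for (mi in seq_along(mols)) {
        if (grp > 0L) {
          known <- grp_mol[as.character(grp)]
          if (!is.na(known) && known != mi) next
          if (is.na(known) && mi %in% grp_mol[names(grp_mol) != as.character(grp)]) next
        }
        if (!boolean_match(comp$query, mols[[mi]])) next
        g2 <- grp_mol
        if (grp > 0L) g2[as.character(grp)] <- mi
        if (assign_ok(ci + 1L, g2)) return(TRUE)
      }
      FALSE
    }
    grps <- unique(vapply(comps, function(cc) cc$group, integer(1)))
    grps <- grps[grps > 0L]
    init <- stats::setNames(rep(NA_integer_, length(grps)), as.character(grps))
    assign_ok(1L, init)
  }
  side_ok(query$reactant, target$reactants) &&
    side_ok(query$product, target$products)
}

## Split a query molecule into connected components (sub-queries), keeping
## each component's group id.
query_components <- function(q) {
  nq <- n_query_atoms(q)
  if (nq == 0L) return(list())
  adj <- query_adjacency(q)
  comp <- integer(nq); ci <- 0L
  for (s in seq_len(nq)) {
    if (comp[s] != 0L) next
    ci <- ci + 1L
    stack <- s
    while (length(stack)) {
      a <- stack[1]; stack <- stack[-1]
      if (comp[a] != 0L) next
      comp[a] <- ci
      stack <- c(stack, adj[[a]][comp[adj[[a]]] == 0L])
    }
  }
  lapply(seq_len(ci), function(cc) {
    keep <- which(comp == cc)
    remap <- match(seq_len(nq), keep)
    bkeep <- which(q$bonds$a1 %in% keep)
    sub <- structure(list(
      atoms = q$atoms[keep],
      bonds = data.frame(a1 = remap[q$bonds$a1[bkeep]], a2 = remap[q$bonds$a2[bkeep]]),
      bexprs = q$bexprs[bkeep],
      maps = q$maps[keep],
      comp = rep(0L, length(keep)),
      neigh = lapply(q$neigh[keep], function(v) ifelse(v > 0L, remap[pmax(v, 1L)], 0L)),
      bond_from = remap[q$bond_from[bkeep]],
      src = ""), class = "query_molecule")
    list(query = sub, group = q$comp[keep[1]])
  })
}

#' Identity of two concrete reactions
#'
#' True iff the canonical-SMILES multisets of the reactants and of the
#' products coincide (order-independent; stereo-equivalent spellings of the
#' same molecule compare equal through canonicalization).
#'
#' @param a,b [concrete_reaction] objects.
#' @return `TRUE` or `FALSE`.
#' @export
reaction_identity <- function(a, b) {
  canon_multiset <- function(mols)
    sort(vapply(mols, write_smiles, character(1), canonical = TRUE))
  identical(canon_multiset(a$reactants), canon_multiset(b$reactants)) &&
    identical(canon_multiset(a$products), canon_multiset(b$products))
}
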