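#' Substructure matching
#'
#' Enumerates all injective, adjacency-preserving mappings of a
#' [query_molecule][parse_smarts] onto a target [molecule] by backtracking.
#' Disconnected queries are matched component by component; when the query
#' carries component groups (zero-level parentheses), all atoms of one group
#' must map into a single target component and distinct groups into distinct
#' target components. The result order is deterministic: matches are sorted
#' by their target-atom tuple in query-atom order.
#'
#' @param query a `query_molecule`.
#' @param target a configured `molecule`.
#' @param root optional target atom index the first query atom must map to
#'   (used by recursive SMARTS evaluation).
#' @param ctx optional precomputed match context (internal).
#' @return A list of matches; each match is a list with `pairs` (integer
#'   vector, `pairs[q]` = target atom of query atom `q`) and `atom_set`
#'   (sorted unique target atoms covered).
#' @export
#' @examples
#' length(find_matches(parse_smarts("CCN"), parse_smiles("NC1CCCCC1N")))  # 4
find_matches <- function(query, target, root = NULL, ctx = NULL) {
  if (is.null(ctx)) ctx <- match_context(target)
  enumerate_matches(query, ctx, root = root, first_only = FALSE)
}

#' Existence-only substructure test
#'
#' Short-circuits after the first embedding of `query` in `target`.
#'
#' @inheritParams find_matches
#' @return `TRUE` or `FALSE`.
#' @export
boolean_match <- function(query, target, root = NULL, ctx = NULL) {
  if (is.null(ctx)) ctx <- match_context(target)
  length(enumerate_matches(query, ctx, root = root, first_only = TRUE)) > 0L
}

#' Matching with component-level grouping
#'
#' Same as [find_matches] but named for the component-level-grouping
#' contract: group constraints from zero-level parentheses are enforced
#' (they are also enforced by `find_matches` itself whenever groups are
#' present).
#'
#' @inheritParams find_matches
#' @return As [find_matches].
#' @export
match_with_clg <- function(query, target) find_matches(query, target)

enumerate_matches <- function(query, ctx, root = NULL, first_only = FALSE) {
  nq <- n_query_atoms(query)
  if (nq == 0L) return(list())
  nt <- n_atoms(ctx$mol)
  if (nt == 0L) return(list())
  qadj <- query_adjacency(query)
  order_q <- query_order(query, qadj, root = root)
  qbond_at <- function(a, b) {
    k <- which((query$bonds$a1 == a & query$bonds$a2 == b) |
               (query$bonds$a1 == b & query$bonds$a2 == a))
    k[1]
  }
  has_chiral <- vapply(query$atoms, function(e) extract_chirality(e) != 0L, logical(1))
  results <- list()
  mapping <- rep(NA_integer_, nq)
  used <- logical(nt)
  group_comp <- integer(0)      # target component chosen per query group

  try_atom <- function(pos) {
    if (pos > nq) {
      # complete: re-check chirality primitives with the full mapping
      if (any(has_chiral)) {
        for (qi in which(has_chiral)) {
          if (!eval_aexpr(query$atoms[[qi]], ctx, mapping[qi],
                          mapping = mapping, qmol = query, qi = qi))
            return(FALSE)
        }
      }
      results[[length(results) + 1L]] <<-
        list(pairs = mapping, atom_set = sort(unique(mapping)))
      return(first_only)
    }
    qi <- order_q[pos]
    grp <- query$comp[qi]
    mapped_nb <- qadj[[qi]][!is.na(mapping[qadj[[qi]]])]
    cands <- if (length(mapped_nb)) {
      # must be adjacent to the image of the first mapped neighbour
      t0 <- mapping[mapped_nb[1]]
      b <- ctx$mol$bonds
      nb <- c(b$a2[b$a1 == t0], b$a1[b$a2 == t0])
      sort(nb)
    } else if (pos == 1L && !is.null(root)) root
    else seq_len(nt)
    for (t in cands) {
      if (used[t]) next
      # component-level grouping constraints
      if (grp > 0L) {
        tc <- ctx$comp[t]
        known <- group_comp[as.character(grp)]
        if (!is.na(known) && known != tc) next
        if (is.na(known) && tc %in% group_comp[names(group_comp) != as.character(grp)]) next
      }
      if (!eval_aexpr(query$atoms[[qi]], ctx, t)) next
      ok <- TRUE
      for (nb in qadj[[qi]]) {
        if (is.na(mapping[nb])) next
        tb <- ctx$bmat[t, mapping[nb]]
        if (tb == 0L || !eval_bexpr(query$bexprs[[qbond_at(qi, nb)]], ctx, tb)) { ok <- FALSE; break }
      }
      if (!ok) next
      mapping[qi] <<- t; used[t] <<- TRUE
      saved <- group_comp
      if (grp > 0L && is.na(group_comp[as.character(grp)]))
        group_comp[as.character(grp)] <<- ctx$comp[t]
      stop_now <- try_atom(pos + 1L)
      mapping[qi] <<- NA_integer_; used[t] <<- FALSE
      group_comp <<- saved
      if (isTRUE(stop_now)) return(TRUE)
    }
    FALSE
  }
  group_comp <- stats::setNames(rep(NA_integer_, max(c(0L, query$comp))),
                                as.character(seq_len(max(c(0L, query$comp)))))
  try_atom(1L)
  sort_matches(results)
}

query_adjacency <- function(query) {
  nq <- n_query_atoms(query)
  adj <- rep(list(integer()), nq)
  for (k in seq_len(nrow(query$bonds))) {
    adj[[query$bonds$a1[k]]] <- c(adj[[query$bonds$a1[k]]], query$bonds$a2[k])
    adj[[query$bonds$a2[k]]] <- c(adj[[query$bonds$a2[k]]], query$bonds$a1[k])
  }
  adj
}

## Visit order: start from atom 1 (or, with a root constraint, keep atom 1
## first), then grow so that each atom connects to an earlier one when its
## component allows it.
query_order <- function(query, qadj, root = NULL) {
  nq <- n_query_atoms(query)
  order_q <- integer(0)
  placed <- logical(nq)
  repeat {
    rem <- which(!placed)
    if (!length(rem)) break
    start <- rem[1]
    order_q <- c(order_q, start); placed[start] <- TRUE
    repeat {
      frontier <- which(!placed & vapply(seq_len(nq), function(a)
        any(placed[qadj[[a]]]), logical(1)))
      if (!length(frontier)) break
      nxt <- frontier[1]
      order_q <- c(order_q, nxt); placed[nxt] <- TRUE
    }
  }
  order_q
}

sort_matches <- function(matches) {
  if (length(matches) <= 1L) return(matches)
  keys <- vapply(matches, function(m) paste(sprintf("%05d", m$pairs), collapse = ","),
                 character(1))
  matches[order(keys)]
}

#' Filter a match list by search mode
#'
#' Implements the site-selection modes: `ALL` (identity), `SINGLE` (first
#' match), `NON_IDENTICAL` (distinct target atom sets; duplicates collapse
#' to the first), `NON_OVERLAPPING` (a maximum family of pairwise-disjoint
#' matches, preferring earlier-enumerated members), `NON_EQUIVALENT` (one
#' representative per fragment-equivalence class, where two matches are
#' equivalent iff the multisets of (query atom, target equivalence class)
#' pairs coincide), and `NON_IDENTICAL_FIRST` (first of the non-identical
#' list).
#'
#' @param matches a list of matches from one [find_matches] call.
#' @param mode one of `"ALL"`, `"SINGLE"`, `"NON_OVERLAPPING"`,
#'   `"NON_IDENTICAL"`, `"NON_EQUIVALENT"`, `"NON_IDENTICAL_FIRST"`.
#' @param equivalence atom-to-class map from [equivalence_classes], required
#'   for `NON_EQUIVALENT`.
#' @return The filtered list of matches (always a subset of the input).
#' @export
filter_mode <- function(matches, mode = c("ALL", "SINGLE", "NON_OVERLAPPING",
                                          "NON_IDENTICAL", "NON_EQUIVALENT",
                                          "NON_IDENTICAL_FIRST"),
                        equivalence = NULL) {
  mode <- match.arg(mode)
  if (!length(matches)) return(matches)
  switch(mode,
    ALL = matches,
    SINGLE = matches[1],
    NON_IDENTICAL = {
      keys <- vapply(matches, function(m) paste(m$atom_set, collapse = ","), character(1))
      matches[!duplicated(keys)]
    },
    NON_IDENTICAL_FIRST = filter_mode(matches, "NON_IDENTICAL")[1],
    NON_OVERLAPPING = non_overlapping_family(matches),
    NON_EQUIVALENT = {
      if (is.null(equivalence))
        stop("NON_EQUIVALENT mode needs an equivalence-class map")
      keys <- vapply(matches, function(m)
        paste(sort(paste(seq_along(m$pairs), equivalence[m$pairs], sep = ">")),
              collapse = ","), character(1))
      matches[!duplicated(keys)]
    })
}

## Maximum family of pairwise-disjoint matches (exact search, preferring
## earlier enumeration order among families of equal size). Falls back to
## greedy selection for very long match lists.
non_overlapping_family <- function(matches) {
  n <- length(matches)
  if (n > 60L) {
    kept <- list(); covered <- integer(0)
    for (m in matches) {
      if (!any(m$atom_set %in% covered)) {
        kept[[length(kept) + 1L]] <- m
        covered <- c(covered, m$atom_set)
      }
    }
    return(kept)
  }
  best <- integer(0)
  recurse <- function(i, chosen, covered) {
    if (length(chosen) + (n - i + 1L) <= length(best)) return(invisible(NULL))
    if (i > n) {
      if (length(chosen) > length(best)) best <<- chosen
      return(invisible(NULL))
    }
    if (!any(matches[[i]]$atom_set %in% covered))
      recurse(i + 1L, c(chosen, i), c(covered, matches[[i]]$atom_set))
    recurse(i + 1L, chosen, covered)
  }
  recurse(1L, integer(0), integer(0))
  matches[best]
}

#' Topological equivalence classes of atoms
#'
#' Two atoms are in the same class iff some graph automorphism respecting
#' element, charge, isotope, implicit hydrogen count, bond orders and
#' aromatic flags maps one onto the other. Orbits are computed by
#' enumerating all attribute-preserving automorphisms with the backtracking
#' matcher.
#'
#' @param mol a [molecule].
#' @return Integer vector: class id per atom (classes numbered by first
#'   member).
#' @export
#' @examples
#' equivalence_classes(parse_smiles("c1ccccc1"))  # all six carbons one class
equivalence_classes <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(integer(0))
  autos <- automorphisms(mol)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (p in autos) for (i in seq_len(n)) {
    ri <- find(i); rj <- find(p[i])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

## All attribute-preserving automorphisms of a molecule, as permutations.
automorphisms <- function(mol) {
  q <- molecule_as_query(mol)
  ms <- find_matches(q, mol)
  lapply(ms, function(m) m$pairs)
}

## Exact-attribute query for self-matching: element, charge, isotope-free
## comparison (isotopes included via charge of 0 trick is wrong, so a
## dedicated primitive set is composed per atom).
molecule_as_query <- function(mol) {
  n <- n_atoms(mol)
  atoms <- vector("list", n)
  for (i in seq_len(n)) {
    parts <- list(leaf("element", mol$atoms$element[i],
                       arom = mol$atoms$aromatic[i]),
                  leaf("charge", mol$atoms$charge[i]),
                  leaf("implH", mol$atoms$nH[i]))
    atoms[[i]] <- expr_join("and", parts)
  }
  bexprs <- vector("list", n_bonds(mol))
  for (k in seq_len(n_bonds(mol))) {
    bexprs[[k]] <- if (mol$bonds$aromatic[k]) leaf("aromatic")
                   else switch(mol$bonds$order[k], leaf("single"), leaf("double"), leaf("triple"))
  }
  structure(list(atoms = atoms,
                 bonds = mol$bonds[, c("a1", "a2")],
                 bexprs = bexprs,
                 maps = rep(0L, n), comp = rep(0L, n),
                 neigh = rep(list(integer()), n), src = ""),
            class = "query_molecule")
}
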