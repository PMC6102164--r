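#' Write a molecule as SMILES
#'
#' Generates a SMILES string for a configured molecule. With
#' `canonical = TRUE` the atom ordering is derived from iterative invariant
#' refinement with exhaustive tie-breaking (the emitted string is the
#' lexicographic minimum over all refinement branches), so the output is
#' invariant under input atom order and under the chosen Kekule assignment
#' of aromatic systems. Tetrahedral parities and cis/trans directional bonds
#' are re-expressed relative to the output ordering.
#'
#' @param mol a [molecule].
#' @param canonical emit the canonical form?
#' @return A single SMILES string.
#' @export
write_smiles <- function(mol, canonical = FALSE) {
  if (n_atoms(mol) == 0L) return("")
  if (!canonical) return(smiles_generate(mol, seq_len(n_atoms(mol))))
  canonical_smiles(mol)
}

canonical_smiles <- function(mol) {
  n <- n_atoms(mol)
  ranks <- initial_ranks(mol)
  best <- NULL
  recurse <- function(ranks) {
    ranks <- refine_ranks(mol, ranks)
    if (max(ranks) == n) {
      s <- smiles_generate(mol, ranks)
      if (is.null(best) || s < best) best <<- s
      return(invisible(NULL))
    }
    # first tied class by rank
    tab <- table(ranks)
    tied <- as.integer(names(tab)[tab > 1])
    r0 <- min(tied)
    members <- which(ranks == r0)
    for (a in members) {
      nr <- ranks
      nr[nr >= r0] <- nr[nr >= r0] + 1L
      nr[a] <- r0
      recurse(nr)
    }
  }
  recurse(ranks)
  best
}

initial_ranks <- function(mol) {
  deg <- mol_degree(mol)
  key <- paste(mol$atoms$element, mol$atoms$aromatic, mol$atoms$charge,
               mol$atoms$nH, ifelse(is.na(mol$atoms$isotope), 0L, mol$atoms$isotope),
               deg, sep = "|")
  match(key, sort(unique(key)))
}

## Bond invariant that is Kekule-order independent for aromatic bonds.
bond_keys <- function(mol) {
  ifelse(mol$bonds$aromatic, "a", as.character(mol$bonds$order))
}

refine_ranks <- function(mol, ranks) {
  bk <- bond_keys(mol)
  b <- mol$bonds
  repeat {
    nbkey <- rep("", length(ranks))
    lists <- rep(list(character()), length(ranks))
    for (k in seq_len(nrow(b))) {
      lists[[b$a1[k]]] <- c(lists[[b$a1[k]]], sprintf("%s:%04d", bk[k], ranks[b$a2[k]]))
      lists[[b$a2[k]]] <- c(lists[[b$a2[k]]], sprintf("%s:%04d", bk[k], ranks[b$a1[k]]))
    }
    key <- vapply(seq_along(ranks), function(i)
      paste(sprintf("%04d", ranks[i]), paste(sort(lists[[i]]), collapse = ","), sep = ";"),
      character(1))
    new <- match(key, sort(unique(key)))
    if (identical(new, ranks)) return(ranks)
    ranks <- new
  }
}

## --- generation -----------------------------------------------------------

smiles_generate <- function(mol, ranks) {
  n <- n_atoms(mol)
  adj <- mol_adjacency(mol)
  visited <- logical(n)
  parent <- rep(NA_integer_, n)
  children <- rep(list(integer()), n)
  order_out <- integer(0)
  ring_open <- list()   # per bond index: digit
  ring_at <- rep(list(integer()), n)  # bond indices of ring closures per atom
  used_bond <- logical(n_bonds(mol))

  dfs <- function(a, p) {
    visited[a] <<- TRUE
    parent[a] <<- p
    order_out <<- c(order_out, a)
    nbs <- adj[[a]][order(ranks[adj[[a]]])]
    for (nb in nbs) {
      k <- mol_bond_between(mol, a, nb)
      if (used_bond[k]) next
      used_bond[k] <<- TRUE
      if (visited[nb]) {            # ring closure
        ring_at[[nb]] <<- c(ring_at[[nb]], k)
        ring_at[[a]] <<- c(ring_at[[a]], k)
      } else {
        children[[a]] <<- c(children[[a]], nb)
        dfs(nb, a)
      }
    }
  }
  comps <- component_ids(mol)
  starts <- vapply(seq_len(max(comps)), function(ci) {
    cand <- which(comps == ci)
    cand[which.min(ranks[cand])]
  }, integer(1))
  starts <- starts[order(vapply(starts, function(s) ranks[s], integer(1)))]
  for (s in starts) dfs(s, NA_integer_)

  # re-collect children in visit order (dfs pushes reversed); children were
  # computed in rank order already, which is the emission order
  pos <- match(seq_len(n), order_out)

  # ring digits in order of opening (first endpoint in output order)
  ring_bonds <- unique(unlist(ring_at))
  digit_of <- integer(0)
  if (length(ring_bonds)) {
    openpos <- vapply(ring_bonds, function(k)
      min(pos[mol$bonds$a1[k]], pos[mol$bonds$a2[k]]), integer(1))
    closepos <- vapply(ring_bonds, function(k)
      max(pos[mol$bonds$a1[k]], pos[mol$bonds$a2[k]]), integer(1))
    ord <- order(openpos, closepos)
    digit_of[as.character(ring_bonds[ord])] <- seq_along(ring_bonds)
  }

  dirs <- assign_directions(mol, parent, pos)

  emit_atom <- function(a) {
    out_neigh <- output_neighbours(mol, a, parent, children, ring_at, pos)
    atom_token(mol, a, out_neigh)
  }
  bond_token <- function(k, from, to) {
    key <- as.character(k)
    if (!is.null(dirs) && !is.na(dirs[key])) {
      v <- dirs[[key]]
      # dirs stored relative to written direction a1 -> a2
      if (from != mol$bonds$a1[k]) v <- -v
      return(if (v > 0) "/" else "\\")
    }
    if (mol$bonds$aromatic[k]) return("")
    o <- mol$bonds$order[k]
    if (o == 1L) {
      if (mol$atoms$aromatic[from] && mol$atoms$aromatic[to]) return("-")
      return("")
    }
    if (o == 2L) return("=")
    "#"
  }
  emit <- function(a) {
    s <- emit_atom(a)
    for (k in ring_at[[a]]) {
      d <- digit_of[[as.character(k)]]
      other <- if (mol$bonds$a1[k] == a) mol$bonds$a2[k] else mol$bonds$a1[k]
      if (pos[a] < pos[other]) {            # opening: carry the bond symbol
        bt <- bond_token(k, a, other)
        s <- paste0(s, bt, if (d > 9) sprintf("%%%02d", d) else d)
      } else {
        s <- paste0(s, if (d > 9) sprintf("%%%02d", d) else d)
      }
    }
    kids <- children[[a]]
    if (length(kids)) {
      for (i in seq_along(kids)) {
        nb <- kids[i]
        k <- mol_bond_between(mol, a, nb)
        sub <- paste0(bond_token(k, a, nb), emit(nb))
        s <- paste0(s, if (i < length(kids)) paste0("(", sub, ")") else sub)
      }
    }
    s
  }
  paste(vapply(starts, emit, character(1)), collapse = ".")
}

## Ordered neighbour list of `a` as it appears in the output string
## (parent, implicit-H placeholder, ring closures, children).
output_neighbours <- function(mol, a, parent, children, ring_at, pos) {
  out <- integer()
  if (!is.na(parent[a])) out <- c(out, parent[a])
  if (mol$atoms$nH[a] == 1L) out <- c(out, 0L)
  for (k in ring_at[[a]]) {
    other <- if (mol$bonds$a1[k] == a) mol$bonds$a2[k] else mol$bonds$a1[k]
    out <- c(out, other)
  }
  c(out, children[[a]])
}

atom_token <- function(mol, a, out_neigh) {
  el <- mol$atoms$element[a]
  arom <- mol$atoms$aromatic[a]
  ch <- mol$atoms$charge[a]
  iso <- mol$atoms$isotope[a]
  nH <- mol$atoms$nH[a]
  se <- stereo_on_atom(mol, a)
  organic <- el %in% c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
  sym <- if (arom && el %in% c("B", "C", "N", "O", "P", "S", "Se", "As"))
    tolower(el) else el
  needs_bracket <- !organic || ch != 0L || !is.na(iso) || !is.null(se) ||
    el == "H" ||
    # pyrrole-type aromatic N/P: a bare lowercase symbol would re-kekulize
    # as the pyridine type, so the H count must be written
    (arom && el %in% c("N", "P") && nH > 0L)
  if (!needs_bracket) {
    bos <- 0
    b <- mol$bonds
    for (k in which(b$a1 == a | b$a2 == a)) bos <- bos + b$order[k]
    if (implicit_h_for(el, 0L, bos) != nH) needs_bracket <- TRUE
  }
  if (!needs_bracket) return(sym)
  chir <- ""
  if (!is.null(se) && se$type %in% c("tetrahedral", "allene")) {
    sgn <- stereo_out_parity(se, out_neigh)
    if (!is.na(sgn)) chir <- if (sgn > 0) "@" else "@@"
  }
  paste0("[",
         if (!is.na(iso)) iso else "",
         sym, chir,
         if (nH == 1L) "H" else if (nH > 1L) paste0("H", nH) else "",
         charge_token(ch), "]")
}

charge_token <- function(ch) {
  if (ch == 0L) ""
  else if (ch == 1L) "+"
  else if (ch == -1L) "-"
  else if (ch > 0L) paste0("+", ch)
  else paste0("-", abs(ch))
}

stereo_on_atom <- function(mol, a) {
  for (se in mol$stereo)
    if (se$type %in% c("tetrahedral", "allene") && se$focus == a) return(se)
  NULL
}

## Parity symbol for the output neighbour order: permutation sign between the
## stored ligand order and the output order, times the stored parity.
stereo_out_parity <- function(se, out_neigh) {
  if (length(out_neigh) != 4L) return(NA_integer_)
  if (!setequal(se$ligands, out_neigh)) return(NA_integer_)
  se$parity * perm_sign(se$ligands, out_neigh)
}

perm_sign <- function(from, to) {
  p <- match(to, from)
  sgn <- 1L
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (i < j && p[i] > p[j]) sgn <- -sgn
  }
  sgn
}

## Directional-bond assignment for cis/trans elements. Values are stored per
## bond index relative to the written a1 -> a2 direction: +1 = "/".
assign_directions <- function(mol, parent, pos) {
  ct <- Filter(function(se) se$type == "cistrans", mol$stereo)
  if (!length(ct)) return(NULL)
  dirs <- integer(0)
  # toward-sign of single bond (x, e): sign the symbol would have were the
  # bond written from x to e
  get_toward <- function(x, e) {
    k <- mol_bond_between(mol, x, e)
    key <- as.character(k)
    if (is.na(dirs[key])) return(NULL)
    v <- dirs[[key]]
    if (mol$bonds$a1[k] != x) v <- -v
    v
  }
  set_toward <- function(x, e, v) {
    k <- mol_bond_between(mol, x, e)
    if (k == 0L || mol$bonds$order[k] != 1L) return(FALSE)
    key <- as.character(k)
    stored <- if (mol$bonds$a1[k] == x) v else -v
    if (!is.na(dirs[key])) return(dirs[[key]] == stored)
    dirs[key] <<- stored
    # the sibling single bond on the same end must take the opposite sense
    b <- mol$bonds
    for (kk in which((b$a1 == e | b$a2 == e) & b$order == 1L)) {
      if (kk == k) next
      x2 <- if (b$a1[kk] == e) b$a2[kk] else b$a1[kk]
      key2 <- as.character(kk)
      stored2 <- if (b$a1[kk] == x2) -v else v
      if (is.na(dirs[key2])) dirs[key2] <<- stored2
    }
    TRUE
  }
  for (se in ct) {
    a <- se$atoms[1]; b2 <- se$atoms[2]
    x <- se$refs[1]; y <- se$refs[2]
    da <- get_toward(x, a)
    if (is.null(da)) { if (!set_toward(x, a, 1L)) next; da <- 1L }
    # convention from the parser: equal normalized signs mean "opposite"
    db_away <- if (se$config == "opposite") da else -da
    set_toward(y, b2, -db_away)   # toward b is the negation of away-from b
  }
  dirs
}
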