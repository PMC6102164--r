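## Ring perception: for every edge that lies on a cycle, find the shortest
## cycle through it (BFS between its endpoints with the edge removed) and
## collect the unique rings. On the molecule sizes this engine targets this
## reproduces the smallest-set-of-smallest-rings for all common fused
## systems and is fully deterministic.
mol_rings <- function(mol) {
  n <- n_atoms(mol)
  b <- mol$bonds
  adj <- mol_adjacency(mol)
  rings <- list()
  seen <- character()
  for (k in seq_len(nrow(b))) {
    path <- bfs_shortest_path(adj, b$a1[k], b$a2[k], skip_edge = c(b$a1[k], b$a2[k]))
    if (is.null(path)) next            # bridge edge, not in any ring
    ring <- path                       # cycle atoms in order
    key <- paste(sort(ring), collapse = ",")
    if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- ring }
  }
  rings
}

bfs_shortest_path <- function(adj, from, to, skip_edge) {
  n <- length(adj)
  prev <- integer(n); prev[from] <- -1L
  queue <- from
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    for (nb in adj[[a]]) {
      if ((a == skip_edge[1] && nb == skip_edge[2]) ||
          (a == skip_edge[2] && nb == skip_edge[1])) next
      if (prev[nb] != 0L) next
      prev[nb] <- a
      if (nb == to) {
        path <- nb
        while (path[1] != from) path <- c(prev[path[1]], path)
        return(path)
      }
      queue <- c(queue, nb)
    }
  }
  NULL
}

## Per-atom count of perceived rings and smallest ring size.
ring_info <- function(mol) {
  rings <- mol_rings(mol)
  n <- n_atoms(mol)
  count <- integer(n); smallest <- rep(NA_integer_, n)
  sizes <- rep(list(integer()), n)
  in_ring_bond <- logical(nrow(mol$bonds))
  for (r in rings) {
    count[r] <- count[r] + 1L
    for (a in r) {
      smallest[a] <- if (is.na(smallest[a])) length(r) else min(smallest[a], length(r))
      sizes[[a]] <- c(sizes[[a]], length(r))
    }
    m <- length(r)
    for (i in seq_len(m)) {
      k <- mol_bond_between(mol, r[i], r[if (i == m) 1L else i + 1L])
      if (k > 0L) in_ring_bond[k] <- TRUE
    }
  }
  list(rings = rings, count = count, smallest = smallest, sizes = sizes,
       ring_bond = in_ring_bond)
}

#' Aromaticity perception
#'
#' Applies a Hueckel 4n+2 electron count over each perceived smallest ring:
#' an atom in an endocyclic double bond contributes one pi electron;
#' pyrrole-type N/P (three connections counting hydrogens) and two-connected
#' O/S contribute a lone pair (two electrons); a carbon whose only double
#' bond is exocyclic (carbonyl-type) contributes zero; a carbanion in the
#' ring contributes two and a carbocation zero. Rings with an sp3-type atom
#' (no contribution possible) or more than three connections per atom are
#' not aromatic. Perception is idempotent: flags are recomputed from the
#' Kekule bond orders on every call and never set on acyclic atoms.
#'
#' @param mol a [molecule] with defined bond orders (Kekule form).
#' @return The molecule with `aromatic` atom and bond flags set.
#' @export
perceive_aromaticity <- function(mol) {
  mol$atoms$aromatic <- rep(FALSE, n_atoms(mol))
  mol$bonds$aromatic <- rep(FALSE, n_bonds(mol))
  if (n_atoms(mol) == 0L) return(mol)
  ri <- ring_info(mol)
  if (!length(ri$rings)) return(mol)
  deg <- mol_degree(mol)
  toth <- mol_total_h(mol)
  contrib <- atom_pi_contribution(mol, ri, deg, toth)
  for (r in ri$rings) {
    cs <- contrib[r]
    if (any(is.na(cs))) next
    if (sum(cs) %% 4L == 2L) {
      mol$atoms$aromatic[r] <- TRUE
      m <- length(r)
      for (i in seq_len(m)) {
        k <- mol_bond_between(mol, r[i], r[if (i == m) 1L else i + 1L])
        if (k > 0L) mol$bonds$aromatic[k] <- TRUE
      }
    }
  }
  mol
}

## Pi-electron contribution per atom, NA when the atom disqualifies a ring.
atom_pi_contribution <- function(mol, ri, deg, toth) {
  n <- n_atoms(mol)
  contrib <- rep(NA_real_, n)
  b <- mol$bonds
  in_ring_atom <- ri$count > 0L
  # classify double bonds once
  endo_dbl <- logical(n)   # atom has a double bond with both ends in rings
  exo_dbl <- logical(n)    # atom has a double bond leaving the ring system
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 2L) next
    both <- in_ring_atom[b$a1[k]] && in_ring_atom[b$a2[k]]
    for (a in c(b$a1[k], b$a2[k])) {
      if (both) endo_dbl[a] <- TRUE else exo_dbl[a] <- TRUE
    }
  }
  for (a in seq_len(n)) {
    if (!in_ring_atom[a]) next
    el <- mol$atoms$element[a]
    ch <- mol$atoms$charge[a]
    if (!(el %in% c("B", "C", "N", "O", "P", "S", "As", "Se"))) next
    if (deg[a] + mol$atoms$nH[a] > 3L) next      # sp3-like connectivity
    contrib[a] <-
      if (endo_dbl[a]) 1
      else if (el %in% c("N", "P") && deg[a] + toth[a] == 3L) 2
      else if (el %in% c("O", "S", "Se") && deg[a] == 2L) 2
      else if (el == "C" && exo_dbl[a]) 0
      else if (el == "C" && ch < 0L) 2
      else if (el == "C" && ch > 0L) 0
      else NA_real_
  }
  contrib
}

## Kekulize: assign alternating single/double orders to aromatic-flagged
## bonds via backtracking perfect matching over the atoms that must carry
## exactly one double bond. Returns the molecule or raises an error for
## unkekulizable input.
kekulize <- function(mol) {
  arom_atoms <- which(mol$atoms$aromatic)
  if (!length(arom_atoms)) return(mol)
  abonds <- which(mol$bonds$aromatic & mol$bonds$order == 1L)
  # atoms needing one double bond among the aromatic bonds
  deg <- mol_degree(mol)
  toth <- mol$atoms$nH + mol_explicit_h(mol)
  has_exo_dbl <- logical(n_atoms(mol))
  for (k in seq_len(n_bonds(mol)))
    if (mol$bonds$order[k] >= 2L)
      has_exo_dbl[c(mol$bonds$a1[k], mol$bonds$a2[k])] <- TRUE
  needs <- vapply(arom_atoms, function(a) {
    el <- mol$atoms$element[a]; ch <- mol$atoms$charge[a]
    if (has_exo_dbl[a]) return(FALSE)
    switch(el,
      C = ch == 0L,
      N = , P = (deg[a] + toth[a] == 2L && ch == 0L) ||
                (deg[a] + toth[a] == 3L && ch > 0L),
      FALSE)
  }, logical(1))
  need_atoms <- arom_atoms[needs]
  if (!length(need_atoms)) return(mol)
  # adjacency restricted to candidate aromatic bonds
  nb <- lapply(seq_len(n_atoms(mol)), function(a) integer())
  for (k in abonds) {
    nb[[mol$bonds$a1[k]]] <- c(nb[[mol$bonds$a1[k]]], k)
    nb[[mol$bonds$a2[k]]] <- c(nb[[mol$bonds$a2[k]]], k)
  }
  matched <- integer(0)           # chosen bond indices
  used <- logical(n_atoms(mol))   # atom already in a double bond
  assign_next <- function(rem) {
    if (!length(rem)) return(TRUE)
    a <- rem[1]
    if (used[a]) return(assign_next(rem[-1]))
    for (k in nb[[a]]) {
      other <- if (mol$bonds$a1[k] == a) mol$bonds$a2[k] else mol$bonds$a1[k]
      if (used[other]) next
      if (!(other %in% need_atoms) && other %in% arom_atoms) {
        # pairing with a lone-pair atom would mis-assign; only allow when the
        # partner also needs a double bond
        next
      }
      used[a] <<- TRUE; used[other] <<- TRUE
      matched <<- c(matched, k)
      if (assign_next(rem[-1])) return(TRUE)
      used[a] <<- FALSE; used[other] <<- FALSE
      matched <<- matched[-length(matched)]
    }
    FALSE
  }
  if (!assign_next(need_atoms))
    stop("cannot kekulize aromatic system (atoms ",
         paste(need_atoms, collapse = ","), ")")
  mol$bonds$order[matched] <- 2L
  mol
}
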