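#' Molecular graph objects
#'
#' A `molecule` is an attributed undirected graph: a data frame of atoms, a
#' data frame of bonds and a list of stereo descriptors. It is the concrete
#' chemistry counterpart of the pattern-side [query_molecule] objects used by
#' SMARTS matching.
#'
#' Atoms carry `element` (symbol), `charge` (formal charge), `isotope`
#' (mass number, `NA` when unset), `nH` (implicit hydrogen count) and
#' `aromatic` (perceived flag). Bonds carry the two endpoint indices
#' (`a1 < a2`), an integer Kekule `order` (1, 2 or 3) and an `aromatic`
#' flag. Stereo descriptors are lists with a `type` of `"tetrahedral"`,
#' `"cistrans"` or `"allene"`; tetrahedral/allene elements store an ordered
#' 4-ligand list (`0` is the reserved placeholder for an implicit hydrogen)
#' and a `parity` of `+1` (anticlockwise, `@`) or `-1` (clockwise, `@@`),
#' interpreted relative to the ligand order (relative stereo representation).
#' Cis/trans elements store the double-bond `atoms`, one reference neighbour
#' on each end (`refs`) and a `config` of `"together"` or `"opposite"`.
#'
#' @param atoms data frame with columns `element`, `charge`, `isotope`,
#'   `nH`, `aromatic`.
#' @param bonds data frame with columns `a1`, `a2`, `order`, `aromatic`.
#' @param stereo list of stereo descriptors.
#' @return An object of class `molecule`.
#' @export
molecule <- function(atoms = empty_atoms(), bonds = empty_bonds(), stereo = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (nrow(bonds)) {
    swap <- bonds$a1 > bonds$a2
    tmp <- bonds$a1[swap]; bonds$a1[swap] <- bonds$a2[swap]; bonds$a2[swap] <- tmp
    if (anyDuplicated(bonds[, c("a1", "a2")]))
      stop("duplicate bond between one atom pair")
    if (any(bonds$a1 == bonds$a2)) stop("bond endpoints must be distinct")
  }
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  structure(list(atoms = atoms, bonds = bonds, stereo = stereo),
            class = "molecule")
}

empty_atoms <- function() {
  data.frame(element = character(), charge = integer(), isotope = integer(),
             nH = integer(), aromatic = logical(), stringsAsFactors = FALSE)
}

empty_bonds <- function() {
  data.frame(a1 = integer(), a2 = integer(), order = integer(),
             aromatic = logical(), stringsAsFactors = FALSE)
}

new_atom_row <- function(element, charge = 0L, isotope = NA_integer_,
                         nH = 0L, aromatic = FALSE) {
  data.frame(element = element, charge = as.integer(charge),
             isotope = as.integer(isotope), nH = as.integer(nH),
             aromatic = aromatic, stringsAsFactors = FALSE)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms, %d bonds, %d stereo element(s)>\n",
              nrow(x$atoms), nrow(x$bonds), length(x$stereo)))
  cat(" ", write_smiles(x), "\n")
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)
n_bonds <- function(mol) nrow(mol$bonds)

## Neighbour map: list (length n atoms) of integer vectors of neighbours.
mol_adjacency <- function(mol) {
  adj <- rep(list(integer()), n_atoms(mol))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], b$a2[k])
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], b$a1[k])
  }
  adj
}

## Index into mol$bonds of the bond joining i and j, or 0L.
mol_bond_between <- function(mol, i, j) {
  lo <- min(i, j); hi <- max(i, j)
  k <- which(mol$bonds$a1 == lo & mol$bonds$a2 == hi)
  if (length(k)) k[1] else 0L
}

mol_degree <- function(mol) {
  d <- integer(n_atoms(mol))
  tb <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = n_atoms(mol))
  d + tb
}

## Sum of Kekule bond orders incident to each atom.
mol_bond_order_sum <- function(mol) {
  s <- numeric(n_atoms(mol))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    s[b$a1[k]] <- s[b$a1[k]] + b$order[k]
    s[b$a2[k]] <- s[b$a2[k]] + b$order[k]
  }
  s
}

## Count of explicit hydrogen neighbours per atom.
mol_explicit_h <- function(mol) {
  cnt <- integer(n_atoms(mol))
  b <- mol$bonds
  ish <- mol$atoms$element == "H"
  for (k in seq_len(nrow(b))) {
    if (ish[b$a2[k]]) cnt[b$a1[k]] <- cnt[b$a1[k]] + 1L
    if (ish[b$a1[k]]) cnt[b$a2[k]] <- cnt[b$a2[k]] + 1L
  }
  cnt
}

## Total hydrogen count (implicit + explicit neighbours).
mol_total_h <- function(mol) mol$atoms$nH + mol_explicit_h(mol)

## Remove atoms (indices) together with incident bonds; stereo elements that
## reference a removed atom are dropped. Remaining atoms are renumbered.
mol_remove_atoms <- function(mol, idx) {
  idx <- unique(as.integer(idx))
  if (!length(idx)) return(mol)
  keep <- setdiff(seq_len(n_atoms(mol)), idx)
  remap <- integer(n_atoms(mol))
  remap[keep] <- seq_along(keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  b <- mol$bonds
  bkeep <- !(b$a1 %in% idx | b$a2 %in% idx)
  bonds <- b[bkeep, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  stereo <- list()
  for (se in mol$stereo) {
    refs <- stereo_atom_refs(se)
    if (any(refs %in% idx)) next
    stereo[[length(stereo) + 1L]] <- remap_stereo(se, remap)
  }
  molecule(atoms, bonds, stereo)
}

## All real atom indices referenced by a stereo element (placeholder 0 skipped).
stereo_atom_refs <- function(se) {
  refs <- switch(se$type,
    tetrahedral = c(se$focus, se$ligands),
    allene      = c(se$focus, se$ligands),
    cistrans    = c(se$atoms, se$refs))
  refs[refs > 0L]
}

remap_stereo <- function(se, remap) {
  rm1 <- function(v) ifelse(v > 0L, remap[pmax(v, 1L)], 0L)
  if (se$type %in% c("tetrahedral", "allene")) {
    se$focus <- remap[se$focus]
    se$ligands <- rm1(se$ligands)
  } else {
    se$atoms <- remap[se$atoms]
    se$refs <- rm1(se$refs)
  }
  se
}

#' Connected components of a molecule
#'
#' Splits a possibly disconnected molecule (for instance the fragmented
#' container produced by applying a reaction with unmapped atoms) into its
#' connected components. Stereo elements travel with the component that owns
#' their atoms.
#'
#' @param mol a [molecule].
#' @return A list of `molecule` objects, ordered by their smallest original
#'   atom index.
#' @export
connected_components <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(list())
  comp <- component_ids(mol)
  lapply(seq_len(max(comp)), function(ci) {
    drop <- which(comp != ci)
    mol_remove_atoms(mol, drop)
  })
}

## Integer component id per atom (1-based, in order of first atom).
component_ids <- function(mol) {
  n <- n_atoms(mol)
  adj <- mol_adjacency(mol)
  comp <- integer(n)
  ci <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    ci <- ci + 1L
    queue <- s
    comp[s] <- ci
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (nb in adj[[a]]) if (comp[nb] == 0L) { comp[nb] <- ci; queue <- c(queue, nb) }
    }
  }
  comp
}

## Graph-isomorphism (with atom/bond attributes and stereo parity) between
## two molecules. Used heavily by tests and reaction identity.
molecules_isomorphic <- function(a, b) {
  if (n_atoms(a) != n_atoms(b) || n_bonds(a) != n_bonds(b)) return(FALSE)
  identical(write_smiles(a, canonical = TRUE), write_smiles(b, canonical = TRUE))
}
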