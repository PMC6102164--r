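## Default-valence model (Daylight organic subset). Each element maps to the
## ordered list of normal valences; implicit H fill picks the smallest one
## that accommodates the current bond-order sum.
default_valences <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L
)

## Valence options adjusted for formal charge: the N/O family gains one bond
## per positive charge and loses one per negative charge; C and B lose
## |charge| (carbanion and carbocation are both trivalent, borate is
## tetravalent via B - charge).
valence_options <- function(element, charge) {
  base <- default_valences[[element]]
  if (is.null(base)) return(NULL)
  v <- switch(element,
    N = , P = , O = , S = base + charge,
    B = base - charge,
    C = base - abs(charge),
    F = , Cl = , Br = , I = , H = base - abs(charge),
    base)
  v[v >= 0L]
}

## Implicit H count for one atom given its bond-order sum (aromatic bonds
## enter with their Kekule order). Over-valent atoms get 0 with a warning.
implicit_h_for <- function(element, charge, bosum) {
  opts <- valence_options(element, charge)
  if (is.null(opts) || !length(opts)) return(0L)
  ok <- opts[opts >= bosum]
  if (!length(ok)) {
    warning(sprintf("atom %s (charge %+d) over-valent (bond order sum %g); 0 implicit H assigned",
                    element, charge, bosum), call. = FALSE)
    return(0L)
  }
  as.integer(min(ok) - bosum)
}

#' Hydrogen management
#'
#' Converts between the two hydrogen representations (implicit counts stored
#' on heavy atoms versus explicit H atoms in the graph) and recomputes
#' implicit counts from the default-valence model.
#'
#' Actions:
#' * `add_implicit`: set `nH` to `default_valence(element, charge) -
#'   bond-order sum`, floored at 0 (explicit H neighbours count towards the
#'   bond-order sum, so they are never double-counted);
#' * `implicit_to_explicit`: append one H atom with a single bond per
#'   implicit hydrogen and re-point tetrahedral placeholders at the new atom;
#' * `explicit_to_implicit`: delete explicit H atoms and fold them back into
#'   `nH` (tetrahedral ligands become placeholders);
#' * `clear_implicit`: zero all `nH`;
#' * `clear_explicit`: delete explicit H atoms without folding.
#'
#' @param mol a [molecule].
#' @param action one of `"add_implicit"`, `"implicit_to_explicit"`,
#'   `"explicit_to_implicit"`, `"clear_implicit"`, `"clear_explicit"`.
#' @return The modified molecule.
#' @export
hydrogens <- function(mol, action = c("add_implicit", "implicit_to_explicit",
                                      "explicit_to_implicit", "clear_implicit",
                                      "clear_explicit")) {
  action <- match.arg(action)
  switch(action,
    add_implicit = {
      bos <- mol_bond_order_sum(mol)
      for (i in seq_len(n_atoms(mol))) {
        if (mol$atoms$element[i] == "H") { mol$atoms$nH[i] <- 0L; next }
        mol$atoms$nH[i] <- implicit_h_for(mol$atoms$element[i],
                                          mol$atoms$charge[i], bos[i])
      }
      mol
    },
    implicit_to_explicit = h_make_explicit(mol),
    explicit_to_implicit = h_make_implicit(mol),
    clear_implicit = { mol$atoms$nH <- 0L; mol },
    clear_explicit = {
      hs <- which(mol$atoms$element == "H" & mol_degree(mol) == 1L)
      mol_remove_atoms(mol, hs)
    })
}

h_make_explicit <- function(mol) {
  nh <- n_atoms(mol)
  for (i in seq_len(nh)) {
    cnt <- mol$atoms$nH[i]
    if (cnt <= 0L) next
    first_new <- NA_integer_
    for (k in seq_len(cnt)) {
      mol$atoms <- rbind(mol$atoms, new_atom_row("H"))
      hidx <- nrow(mol$atoms)
      if (is.na(first_new)) first_new <- hidx
      mol$bonds <- rbind(mol$bonds, data.frame(
        a1 = min(i, hidx), a2 = max(i, hidx), order = 1L, aromatic = FALSE,
        stringsAsFactors = FALSE))
    }
    mol$atoms$nH[i] <- 0L
    # a tetrahedral placeholder on this focus becomes the first new H atom
    for (s in seq_along(mol$stereo)) {
      se <- mol$stereo[[s]]
      if (se$type %in% c("tetrahedral", "allene") && se$focus == i) {
        se$ligands[se$ligands == 0L] <- first_new
        mol$stereo[[s]] <- se
      }
    }
  }
  mol
}

h_make_implicit <- function(mol) {
  deg <- mol_degree(mol)
  hs <- which(mol$atoms$element == "H" & deg == 1L &
                is.na(mol$atoms$isotope) & mol$atoms$charge == 0L)
  if (!length(hs)) return(mol)
  # credit each removed H to its heavy neighbour
  adj <- mol_adjacency(mol)
  heavy <- vapply(hs, function(h) adj[[h]][1], integer(1))
  drop <- hs[mol$atoms$element[heavy] != "H"]
  heavy <- heavy[mol$atoms$element[heavy] != "H"]
  for (s in seq_along(mol$stereo)) {
    se <- mol$stereo[[s]]
    if (se$type %in% c("tetrahedral", "allene")) {
      gone <- se$ligands %in% drop
      if (sum(gone) <= 1L) se$ligands[gone] <- 0L
      mol$stereo[[s]] <- se
    }
  }
  tab <- table(heavy)
  for (nm in names(tab))
    mol$atoms$nH[as.integer(nm)] <- mol$atoms$nH[as.integer(nm)] + as.integer(tab[[nm]])
  mol_remove_atoms(mol, drop)
}
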