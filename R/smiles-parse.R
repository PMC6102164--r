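#' Parse a SMILES string
#'
#' Reads a SMILES string over the supported feature set (organic subset and
#' bracket atoms, branches, ring closures including `%nn`, charges, isotopes,
#' explicit hydrogen counts, `@`/`@@` tetrahedral parities, `/` and `\`
#' directional bonds, dot disconnection) into a configured [molecule]:
#' aromatic lowercase input is kekulized, implicit hydrogen counts are
#' assigned from the default-valence model, aromaticity is perceived, and
#' stereo descriptors are built with ligand order equal to the order of
#' appearance in the string.
#'
#' @param text a single SMILES string.
#' @return A [molecule].
#' @export
#' @examples
#' parse_smiles("NC1CCCCC1N")         # cyclohexane-1,2-diamine
#' parse_smiles("O[C@@H](C)C(O)=O")   # (R)-2-hydroxypropanoic acid
parse_smiles <- function(text) {
  st <- smiles_scan(text)
  mol <- molecule(st$atoms, st$bonds)
  # default bonds between two aromatic atoms are aromatic
  for (k in seq_len(n_bonds(mol))) {
    if (st$bond_sym[k] == "" &&
        mol$atoms$aromatic[mol$bonds$a1[k]] && mol$atoms$aromatic[mol$bonds$a2[k]])
      mol$bonds$aromatic[k] <- TRUE
    if (st$bond_sym[k] == ":") mol$bonds$aromatic[k] <- TRUE
  }
  mol <- kekulize(mol)
  # implicit H for organic-subset atoms (bracket atoms keep the stated count)
  bos <- mol_bond_order_sum(mol)
  for (i in seq_len(n_atoms(mol))) {
    if (st$bracket[i]) next
    mol$atoms$nH[i] <- implicit_h_for(mol$atoms$element[i], mol$atoms$charge[i], bos[i])
  }
  mol <- perceive_aromaticity(mol)
  mol$stereo <- build_stereo(mol, st)
  mol
}

## Character-level scanner; returns atoms/bonds plus parse bookkeeping:
## per-atom chirality, bracket flag and written neighbour order; per-bond
## symbol and written direction.
smiles_scan <- function(text) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  atoms <- empty_atoms()
  bonds <- empty_bonds()
  bond_sym <- character()
  bond_from <- integer()          # written-direction origin atom per bond
  chirality <- integer()          # 0 none, +1 @, -1 @@
  bracket <- logical()
  neigh <- list()                 # per atom: written neighbour order (0 = slot)
  prev <- NA_integer_
  stack <- integer()
  pending <- ""
  rings <- list()                 # open ring closures keyed by digit
  i <- 1
  err <- function(msg, pos) stop(sprintf("SMILES syntax error at position %d: %s", pos, msg), call. = FALSE)

  add_atom <- function(row, chir, is_bracket) {
    atoms <<- rbind(atoms, row)
    ai <- nrow(atoms)
    chirality[ai] <<- chir
    bracket[ai] <<- is_bracket
    neigh[[ai]] <<- integer()
    if (!is.na(prev)) {
      if (pending == ".") {
        # dot: no bond
      } else {
        add_bond(prev, ai, pending)
        neigh[[prev]] <<- c(neigh[[prev]], ai)
        neigh[[ai]] <<- c(neigh[[ai]], prev)
      }
    }
    pending <<- ""
    prev <<- ai
    ai
  }
  add_bond <- function(a, b, sym) {
    order <- switch(sym, "=" = 2L, "#" = 3L, 1L)
    bonds <<- rbind(bonds, data.frame(a1 = min(a, b), a2 = max(a, b),
                                      order = order, aromatic = FALSE,
                                      stringsAsFactors = FALSE))
    bond_sym[nrow(bonds)] <<- sym
    bond_from[nrow(bonds)] <<- a
  }

  while (i <= n) {
    c1 <- chars[i]
    c2 <- if (i < n) chars[i + 1] else ""
    if (c1 %in% c("-", "=", "#", ":", "/", "\\", ".")) {
      pending <- c1; i <- i + 1
    } else if (c1 == "(") {
      if (is.na(prev)) err("branch before any atom", i)
      stack <- c(stack, prev); i <- i + 1
    } else if (c1 == ")") {
      if (!length(stack)) err("unbalanced ')'", i)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1
    } else if (grepl("[0-9%]", c1)) {
      if (c1 == "%") {
        if (!grepl("[0-9]", c2) || i + 2 > n || !grepl("[0-9]", chars[i + 2]))
          err("'%' ring closure needs two digits", i)
        num <- paste0(c2, chars[i + 2]); i <- i + 3
      } else { num <- c1; i <- i + 1 }
      if (is.na(prev)) err("ring closure before any atom", i)
      if (!is.null(rings[[num]])) {
        op <- rings[[num]]
        sym <- if (pending != "") pending else op$sym
        if (op$sym != "" && pending != "" && op$sym != pending &&
            !(sort(c(op$sym, pending))[1] == "/" && sort(c(op$sym, pending))[2] == "\\"))
          err(sprintf("conflicting ring-closure bond symbols '%s'/'%s'", op$sym, pending), i)
        add_bond(op$atom, prev, sym)
        neigh[[op$atom]][op$slot] <- prev
        neigh[[prev]] <- c(neigh[[prev]], op$atom)
        rings[[num]] <- NULL
      } else {
        neigh[[prev]] <- c(neigh[[prev]], 0L)  # reserve the slot now
        rings[[num]] <- list(atom = prev, sym = pending, slot = length(neigh[[prev]]))
      }
      pending <- ""
    } else if (c1 == "[") {
      close <- find_bracket_close(chars, i)
      if (is.na(close)) err("unbalanced '['", i)
      body <- paste(chars[(i + 1):(close - 1)], collapse = "")
      ba <- parse_bracket_atom(body, i)
      add_atom(ba$row, ba$chir, TRUE)
      i <- close + 1
    } else if (grepl("[A-Za-z*]", c1)) {
      two <- paste0(c1, c2)
      if (two %in% c("Cl", "Br")) {
        add_atom(new_atom_row(two), 0L, FALSE); i <- i + 2
      } else if (c1 %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(new_atom_row(c1), 0L, FALSE); i <- i + 1
      } else if (c1 %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(new_atom_row(toupper(c1), aromatic = TRUE), 0L, FALSE); i <- i + 1
      } else err(sprintf("unexpected character '%s'", c1), i)
    } else err(sprintf("unexpected character '%s'", c1), i)
  }
  if (length(stack)) err("unbalanced '('", n)
  if (length(rings)) err(sprintf("unclosed ring bond(s): %s", paste(names(rings), collapse = ",")), n)
  if (nrow(atoms) == 0L && nzchar(text)) err("no atoms parsed", 1)
  list(atoms = atoms, bonds = bonds, bond_sym = bond_sym, bond_from = bond_from,
       chirality = chirality, bracket = bracket, neigh = neigh)
}

find_bracket_close <- function(chars, open) {
  j <- open + 1
  while (j <= length(chars)) {
    if (chars[j] == "]") return(j)
    j <- j + 1
  }
  NA_integer_
}

## Bracket atom body: [isotope? symbol chiral? Hn? charge? :map?]
parse_bracket_atom <- function(body, pos) {
  gr <- regmatches(body, regexec(paste0(
    "^([0-9]+)?",                              # isotope
    "(\\*|[A-Z][a-z]?|b|c|n|o|p|s|se|as)",     # element (or aromatic lowercase)
    "(@@|@)?",                                 # chirality
    "(H[0-9]*)?",                              # hydrogen count
    "(\\+{1,3}|-{1,3}|\\+[0-9]|-[0-9])?",      # charge
    "(:[0-9]+)?$"), body))[[1]]
  if (!length(gr))
    stop(sprintf("SMILES syntax error at position %d: bad bracket atom [%s]", pos, body), call. = FALSE)
  iso <- if (nzchar(gr[2])) as.integer(gr[2]) else NA_integer_
  sym <- gr[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  if (aromatic) sym <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  if (sym == "*") stop(sprintf("SMILES syntax error at position %d: wildcard atom not allowed in SMILES", pos), call. = FALSE)
  chir <- if (gr[4] == "@") 1L else if (gr[4] == "@@") -1L else 0L
  nH <- if (!nzchar(gr[5])) 0L
        else if (gr[5] == "H") 1L
        else as.integer(substring(gr[5], 2))
  charge <- parse_charge_token(gr[6])
  list(row = new_atom_row(sym, charge = charge, isotope = iso, nH = nH,
                          aromatic = aromatic),
       chir = chir)
}

parse_charge_token <- function(tok) {
  if (!nzchar(tok)) return(0L)
  sign <- if (substr(tok, 1, 1) == "+") 1L else -1L
  rest <- substring(tok, 2)
  mag <- if (!nzchar(rest)) 1L
         else if (grepl("^[0-9]$", rest)) as.integer(rest)
         else nchar(tok)  # ++ / --- style
  sign * mag
}

## Build tetrahedral / cis-trans / allene stereo descriptors from the parse
## bookkeeping, with ligand order = written order.
build_stereo <- function(mol, st) {
  stereo <- list()
  # tetrahedral and allene centres
  for (a in which(st$chirality != 0L)) {
    lig <- st$neigh[[a]]
    dbl_nb <- double_bond_neighbours(mol, a)
    if (length(dbl_nb) == 2L && length(lig) == 2L) {
      al <- build_allene(mol, st, a, dbl_nb)
      if (!is.null(al)) { al$parity <- st$chirality[a]; stereo[[length(stereo) + 1L]] <- al }
      next
    }
    if (mol$atoms$nH[a] == 1L) {
      # implicit H occupies the slot right after the preceding atom (or
      # first, when the stereo atom starts the string/component)
      at <- if (length(lig) && written_first_is_parent(st, a)) 2L else 1L
      lig <- append(lig, 0L, after = at - 1L)
    }
    if (length(lig) != 4L || anyDuplicated(lig[lig > 0L])) {
      warning(sprintf("ignoring chirality on atom %d: %d ligand(s)", a, length(lig)), call. = FALSE)
      next
    }
    stereo[[length(stereo) + 1L]] <-
      list(type = "tetrahedral", focus = a, ligands = lig,
           parity = st$chirality[a])
  }
  # cis/trans double bonds from directional single bonds
  dir_bonds <- which(st$bond_sym %in% c("/", "\\"))
  if (length(dir_bonds)) {
    for (k in seq_len(n_bonds(mol))) {
      if (mol$bonds$order[k] != 2L || mol$bonds$aromatic[k]) next
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      da <- directional_sign(mol, st, dir_bonds, a, toward = TRUE)
      db <- directional_sign(mol, st, dir_bonds, b, toward = FALSE)
      if (is.null(da) || is.null(db)) next
      config <- if (da$sign == db$sign) "opposite" else "together"
      stereo[[length(stereo) + 1L]] <-
        list(type = "cistrans", atoms = c(a, b), refs = c(da$nb, db$nb),
             config = config)
    }
  }
  stereo
}

written_first_is_parent <- function(st, a) {
  # TRUE when the first recorded neighbour of `a` was written before `a`
  length(st$neigh[[a]]) > 0L && st$neigh[[a]][1] != 0L && st$neigh[[a]][1] < a
}

double_bond_neighbours <- function(mol, a) {
  b <- mol$bonds
  k <- which((b$a1 == a | b$a2 == a) & b$order == 2L)
  vapply(k, function(kk) if (b$a1[kk] == a) b$a2[kk] else b$a1[kk], integer(1))
}

## Directional sign at one end of a double bond, normalized to the chain
## direction through the bond: "toward" the near end for the left side,
## "away from" it for the right side. Equal signs mean opposite (trans).
directional_sign <- function(mol, st, dir_bonds, end, toward) {
  for (k in dir_bonds) {
    a1 <- mol$bonds$a1[k]; a2 <- mol$bonds$a2[k]
    if (a1 != end && a2 != end) next
    nb <- if (a1 == end) a2 else a1
    s <- if (st$bond_sym[k] == "/") 1L else -1L
    written_to_end <- st$bond_from[k] == nb
    if (toward) { if (!written_to_end) s <- -s } else { if (written_to_end) s <- -s }
    return(list(nb = nb, sign = s))
  }
  NULL
}

build_allene <- function(mol, st, focus, terms) {
  lig <- integer()
  for (t in terms) {
    others <- setdiff(st$neigh[[t]], focus)
    others <- others[others > 0L]
    if (mol$atoms$nH[t] == 1L) others <- c(others, 0L)
    if (length(others) < 1L || length(others) > 2L) return(NULL)
    if (length(others) == 1L) others <- c(others, if (others[1] == 0L) return(NULL) else 0L)
    lig <- c(lig, others)
  }
  if (length(lig) != 4L) return(NULL)
  list(type = "allene", focus = focus, ligands = lig, parity = 0L)
}
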