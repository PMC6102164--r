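#' SMARTS query molecules
#'
#' A `query_molecule` is the pattern-side counterpart of a [molecule]: a
#' graph whose atoms are logical atom expressions and whose bonds are
#' logical bond expressions, plus per-atom map indices (`0` = unmapped) and
#' component-group numbers from zero-level parentheses (`0` = ungrouped).
#'
#' @param text a SMARTS string.
#' @return An object of class `query_molecule` with fields `atoms` (list of
#'   atom expressions), `bonds` (data frame `a1`, `a2`), `bexprs` (parallel
#'   list of bond expressions), `maps` (integer map indices), `comp`
#'   (component groups) and `neigh` (written neighbour order per atom).
#' @export
#' @examples
#' q <- parse_smarts("CCN")
#' parse_smarts("[CH3;!$(C*=O);!$(C*N)]")
parse_smarts <- function(text) {
  ps <- smarts_scan(text)
  structure(list(atoms = ps$atoms, bonds = ps$bonds, bexprs = ps$bexprs,
                 maps = ps$maps, comp = ps$comp, neigh = ps$neigh,
                 bond_from = ps$bond_from, src = text),
            class = "query_molecule")
}

#' @export
print.query_molecule <- function(x, ...) {
  cat(sprintf("<query: %d atom(s), %d bond(s)> %s\n",
              length(x$atoms), nrow(x$bonds), unparse_smarts(x)))
  invisible(x)
}

n_query_atoms <- function(q) length(q$atoms)

smarts_scan <- function(text) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  atoms <- list(); maps <- integer(); comp <- integer(); neigh <- list()
  bonds <- data.frame(a1 = integer(), a2 = integer())
  bexprs <- list(); bond_from <- integer()
  prev <- NA_integer_
  stack <- list()
  pending <- NULL            # parsed bond expression or NULL (default)
  pending_dot <- FALSE
  rings <- list()
  group <- 0L                # current zero-level group (0 = none)
  ngroups <- 0L
  depth <- 0L                # branch nesting inside the current group
  i <- 1
  err <- function(msg, pos) stop(sprintf("SMARTS syntax error at position %d: %s", pos, msg), call. = FALSE)

  add_atom <- function(expr, map) {
    atoms[[length(atoms) + 1L]] <<- expr
    ai <- length(atoms)
    maps[ai] <<- map
    comp[ai] <<- group
    neigh[[ai]] <<- integer()
    if (!is.na(prev) && !pending_dot) {
      add_bond(prev, ai, if (is.null(pending)) leaf("default") else pending)
      neigh[[prev]] <<- c(neigh[[prev]], ai)
      neigh[[ai]] <<- c(neigh[[ai]], prev)
    }
    pending <<- NULL; pending_dot <<- FALSE
    prev <<- ai
  }
  add_bond <- function(a, b, expr) {
    bonds <<- rbind(bonds, data.frame(a1 = a, a2 = b))
    bexprs[[nrow(bonds)]] <<- expr
    bond_from[nrow(bonds)] <<- a
  }

  while (i <= n) {
    c1 <- chars[i]
    if (c1 %in% c("-", "=", "#", ":", "~", "/", "\\", "!", "@") ||
        (c1 == "&") || (c1 == ",") || (c1 == ";")) {
      # a bond expression run: consume it whole
      be <- scan_bond_expression(chars, i, err)
      pending <- be$expr
      i <- be$next_i
    } else if (c1 == ".") {
      pending_dot <- TRUE
      prev <- NA_integer_
      i <- i + 1
    } else if (c1 == "(") {
      if (is.na(prev) && depth == 0L) {
        # zero-level parenthesis: component group
        if (group != 0L) err("nested zero-level parentheses", i)
        ngroups <- ngroups + 1L
        group <- ngroups
      } else {
        if (is.na(prev)) err("branch before any atom", i)
        stack[[length(stack) + 1L]] <- prev
        depth <- depth + 1L
      }
      i <- i + 1
    } else if (c1 == ")") {
      if (depth > 0L) {
        prev <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        depth <- depth - 1L
      } else if (group != 0L) {
        group <- 0L
        prev <- NA_integer_
        pending_dot <- TRUE    # after a group only '.' or end is expected
      } else err("unbalanced ')'", i)
      i <- i + 1
    } else if (grepl("[0-9%]", c1)) {
      if (c1 == "%") {
        if (i + 2 > n) err("'%' ring closure needs two digits", i)
        num <- paste0(chars[i + 1], chars[i + 2]); i <- i + 3
      } else { num <- c1; i <- i + 1 }
      if (is.na(prev)) err("ring closure before any atom", i)
      if (!is.null(rings[[num]])) {
        op <- rings[[num]]
        expr <- if (!is.null(pending)) pending
                else if (!is.null(op$expr)) op$expr
                else leaf("default")
        add_bond(op$atom, prev, expr)
        neigh[[op$atom]][op$slot] <- prev
        neigh[[prev]] <- c(neigh[[prev]], op$atom)
        rings[[num]] <- NULL
      } else {
        neigh[[prev]] <- c(neigh[[prev]], 0L)
        rings[[num]] <- list(atom = prev, expr = pending, slot = length(neigh[[prev]]))
      }
      pending <- NULL
    } else if (c1 == "[") {
      close <- matching_bracket(chars, i)
      if (is.na(close)) err("unbalanced '['", i)
      body <- paste(chars[(i + 1):(close - 1)], collapse = "")
      pa <- parse_atom_expression(body, i)
      add_atom(pa$expr, pa$map)
      i <- close + 1
    } else if (c1 == "*") {
      add_atom(leaf("any"), 0L); i <- i + 1
    } else if (c1 == "A") {
      add_atom(leaf("aliphatic"), 0L); i <- i + 1
    } else if (c1 == "a") {
      add_atom(leaf("aromatic"), 0L); i <- i + 1
    } else if (grepl("[A-Za-z]", c1)) {
      c2 <- if (i < n) chars[i + 1] else ""
      two <- paste0(c1, c2)
      if (two %in% c("Cl", "Br")) {
        add_atom(leaf("element", two, arom = FALSE), 0L); i <- i + 2
      } else if (c1 %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(leaf("element", c1, arom = FALSE), 0L); i <- i + 1
      } else if (c1 %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(leaf("element", toupper(c1), arom = TRUE), 0L); i <- i + 1
      } else err(sprintf("unknown primitive '%s'", c1), i)
    } else err(sprintf("unexpected character '%s'", c1), i)
  }
  if (depth > 0L) err("unbalanced '('", n)
  if (length(rings)) err(sprintf("unclosed ring bond(s): %s", paste(names(rings), collapse = ",")), n)
  list(atoms = atoms, bonds = bonds, bexprs = bexprs, maps = maps,
       comp = comp, neigh = neigh, bond_from = bond_from)
}

## '[' ... ']' with nesting through recursive '$(...)'
matching_bracket <- function(chars, open) {
  j <- open + 1; depth <- 0L
  while (j <= length(chars)) {
    if (chars[j] == "(") depth <- depth + 1L
    else if (chars[j] == ")") depth <- depth - 1L
    else if (chars[j] == "]" && depth == 0L) return(j)
    j <- j + 1
  }
  NA_integer_
}

## Bond expression outside brackets: primitives and !,&,',',';' operators.
scan_bond_expression <- function(chars, i, err) {
  toks <- list(); n <- length(chars)
  repeat {
    if (i > n) break
    c1 <- chars[i]
    t <- switch(c1,
      "-" = "single", "=" = "double", "#" = "triple", ":" = "aromatic",
      "~" = "any", "@" = "ring", "/" = "dirup", "\\" = "dirdown",
      "!" = "!", "&" = "&", "," = ",", ";" = ";", NULL)
    if (is.null(t)) break
    # ':' directly followed by a digit after an atom is a map? no: maps only
    # inside brackets; ':' here is always an aromatic bond primitive
    toks[[length(toks) + 1L]] <- t
    i <- i + 1
  }
  if (!length(toks)) err("empty bond expression", i)
  expr <- parse_expr_tokens(unlist(toks), function(tok)
    leaf(tok), err, i)
  list(expr = expr, next_i = i)
}

## Generic precedence-climbing over a token vector where non-operator tokens
## are already primitive names (bonds) or closures producing leaves (atoms).
parse_expr_tokens <- function(tokens, make_leaf, err, pos) {
  idx <- 1L
  peek <- function() if (idx <= length(tokens)) tokens[[idx]] else NULL
  take <- function() { t <- tokens[[idx]]; idx <<- idx + 1L; t }
  is_op <- function(t, ops) is.character(t) && length(t) == 1L && t %in% ops
  parse_not <- function() {
    t <- peek()
    if (identical(t, "!")) { take(); return(expr_not(parse_not())) }
    if (is.null(t) || is_op(t, c("&", ",", ";"))) err("expected primitive", pos)
    make_leaf(take())
  }
  parse_and <- function() {
    args <- list(parse_not())
    repeat {
      t <- peek()
      if (identical(t, "&")) { take(); args[[length(args) + 1L]] <- parse_not() }
      else if (!is.null(t) && !is_op(t, c(",", ";"))) args[[length(args) + 1L]] <- parse_not()
      else break
    }
    expr_join("and", args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (identical(peek(), ",")) { take(); args[[length(args) + 1L]] <- parse_and() }
    expr_join("or", args)
  }
  parse_andlo <- function() {
    args <- list(parse_or())
    while (identical(peek(), ";")) { take(); args[[length(args) + 1L]] <- parse_or() }
    expr_join("andlo", args)
  }
  out <- parse_andlo()
  if (idx <= length(tokens)) err("trailing tokens in expression", pos)
  out
}

## Atom expression inside [...]: tokenize to primitive leaves, then apply
## operator precedence. The trailing :n map index is split off first.
parse_atom_expression <- function(body, pos) {
  map <- 0L
  m <- regmatches(body, regexec("^(.*?):([0-9]+)$", body))[[1]]
  if (length(m) == 3 && !grepl("\\$\\([^)]*$", m[2])) {
    map <- as.integer(m[3]); body <- m[2]
  }
  err <- function(msg, p) stop(sprintf("SMARTS syntax error at position %d: %s", p, msg), call. = FALSE)
  toks <- tokenize_atom_primitives(body, pos, err)
  expr <- parse_expr_tokens(toks, identity, err, pos)
  list(expr = expr, map = map)
}

two_letter_elements <- c("Cl", "Br", "Si", "Se", "As", "Li", "Na", "Mg",
  "Al", "Ca", "Fe", "Cu", "Zn", "Sn", "Ag", "Mn", "Co", "Ni", "He", "Ne",
  "Ar", "Kr", "Xe", "Be", "Ge", "Sb", "Te", "Pt", "Pd", "Au", "Hg", "Pb",
  "Ti", "Cr", "Mo", "Ru", "Rh", "Cd", "Bi")

tokenize_atom_primitives <- function(body, pos, err) {
  chars <- strsplit(body, "")[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1
  first <- TRUE
  read_digits <- function(i, default) {
    j <- i; num <- ""
    while (j <= n && grepl("[0-9]", chars[j])) { num <- paste0(num, chars[j]); j <- j + 1 }
    list(value = if (nzchar(num)) as.integer(num) else default, next_i = j)
  }
  push <- function(x) toks[[length(toks) + 1L]] <<- x
  while (i <= n) {
    c1 <- chars[i]
    c2 <- if (i < n) chars[i + 1] else ""
    if (c1 %in% c("!", "&", ",", ";")) { push(c1); i <- i + 1; first <- FALSE; next }
    consumed <- TRUE
    if (c1 == "*") { push(leaf("any")); i <- i + 1 }
    else if (c1 == "$") {
      if (c2 != "(") err("'$' must be followed by '(smarts)'", pos)
      j <- i + 1; depth <- 0L
      repeat {
        if (j > n) err("unbalanced '(' in recursive expression", pos)
        if (chars[j] == "(") depth <- depth + 1L
        if (chars[j] == ")") { depth <- depth - 1L; if (depth == 0L) break }
        j <- j + 1
      }
      sub <- paste(chars[(i + 2):(j - 1)], collapse = "")
      push(leaf("recursive", parse_smarts(sub)))
      i <- j + 1
    }
    else if (c1 == "@") {
      if (c2 == "@") { push(leaf("chiral", -1L)); i <- i + 2 }
      else { push(leaf("chiral", 1L)); i <- i + 1 }
    }
    else if (c1 == "#") {
      d <- read_digits(i + 1, NA)
      if (is.na(d$value)) err("'#' needs an atomic number", pos)
      push(leaf("element", element_symbols[d$value], arom = NA))
      i <- d$next_i
    }
    else if (c1 == "+" || c1 == "-") {
      sgn <- if (c1 == "+") 1L else -1L
      j <- i + 1; reps <- 1L
      while (j <= n && chars[j] == c1) { reps <- reps + 1L; j <- j + 1 }
      if (reps == 1L && j <= n && grepl("[0-9]", chars[j])) {
        d <- read_digits(j, 1L)
        push(leaf("charge", sgn * d$value)); i <- d$next_i
      } else {
        push(leaf("charge", sgn * reps)); i <- j
      }
    }
    else if (c1 == "H" && !first) {
      d <- read_digits(i + 1, 1L); push(leaf("totalH", d$value)); i <- d$next_i
    }
    else if (c1 == "h") {
      d <- read_digits(i + 1, 1L); push(leaf("implH", d$value)); i <- d$next_i
    }
    else if (c1 == "X") {
      d <- read_digits(i + 1, 1L); push(leaf("connectivity", d$value)); i <- d$next_i
    }
    else if (c1 == "D") {
      d <- read_digits(i + 1, 1L); push(leaf("degree", d$value)); i <- d$next_i
    }
    else if (c1 == "R") {
      d <- read_digits(i + 1, NA); push(leaf("ring_count", d$value)); i <- d$next_i
    }
    else if (c1 == "r") {
      d <- read_digits(i + 1, NA)
      push(if (is.na(d$value)) leaf("ring_count", NA) else leaf("ring_size", d$value))
      i <- d$next_i
    }
    else if (c1 == "v") {
      d <- read_digits(i + 1, 1L); push(leaf("valence", d$value)); i <- d$next_i
    }
    else if (c1 == "A") { push(leaf("aliphatic")); i <- i + 1 }
    else if (c1 == "a" && !paste0(c1, c2) %in% c("as")) { push(leaf("aromatic")); i <- i + 1 }
    else if (grepl("[0-9]", c1)) err("isotope primitives are not supported in queries", pos)
    else consumed <- FALSE
    if (consumed) { first <- FALSE; next }
    # element symbols
    two <- paste0(c1, c2)
    if (two %in% two_letter_elements) {
      push(leaf("element", two, arom = FALSE)); i <- i + 2
    } else if (two %in% c("se", "as")) {
      push(leaf("element", paste0(toupper(c1), c2), arom = TRUE)); i <- i + 2
    } else if (c1 == "H" && first) {
      # leading H: hydrogen element unless followed by a count digit
      if (grepl("[0-9]", c2)) {
        d <- read_digits(i + 1, 1L); push(leaf("totalH", d$value)); i <- d$next_i
      } else {
        push(leaf("element", "H", arom = FALSE)); i <- i + 1
      }
    } else if (grepl("[A-Z]", c1)) {
      push(leaf("element", c1, arom = FALSE)); i <- i + 1
    } else if (c1 %in% c("b", "c", "n", "o", "p", "s")) {
      push(leaf("element", toupper(c1), arom = TRUE)); i <- i + 1
    } else err(sprintf("unknown atom primitive '%s'", c1), pos)
    first <- FALSE
  }
  if (!length(toks)) err("empty atom expression", pos)
  toks
}

## --- unparser -------------------------------------------------------------

#' Render a query molecule back to a normalized SMARTS string
#'
#' Atoms are emitted as bracket expressions in normalized form (primitives
#' sorted within each operator level), so `parse_smarts(unparse_smarts(q))`
#' is stable and two structurally identical queries render identically.
#'
#' @param q a [query_molecule][parse_smarts].
#' @return A SMARTS string.
#' @export
unparse_smarts <- function(q) {
  nq <- n_query_atoms(q)
  if (nq == 0L) return("")
  adj <- rep(list(integer()), nq)
  for (k in seq_len(nrow(q$bonds))) {
    adj[[q$bonds$a1[k]]] <- c(adj[[q$bonds$a1[k]]], q$bonds$a2[k])
    adj[[q$bonds$a2[k]]] <- c(adj[[q$bonds$a2[k]]], q$bonds$a1[k])
  }
  visited <- logical(nq)
  used <- logical(nrow(q$bonds))
  children <- rep(list(integer()), nq)
  ring_tok <- rep(list(character()), nq)
  digit <- 0L
  bond_at <- function(a, b) {
    k <- which((q$bonds$a1 == a & q$bonds$a2 == b) | (q$bonds$a1 == b & q$bonds$a2 == a))
    k[1]
  }
  # pass 1: DFS tree and ring-closure digits
  walk <- function(a) {
    visited[a] <<- TRUE
    for (nb in adj[[a]]) {
      k <- bond_at(a, nb)
      if (used[k]) next
      used[k] <<- TRUE
      if (visited[nb]) {
        digit <<- digit + 1L
        d <- if (digit > 9) sprintf("%%%02d", digit) else as.character(digit)
        bt <- bond_qtoken(q$bexprs[[k]])
        ring_tok[[nb]] <<- c(ring_tok[[nb]], paste0(bt, d))
        ring_tok[[a]] <<- c(ring_tok[[a]], d)
      } else {
        children[[a]] <<- c(children[[a]], nb)
        walk(nb)
      }
    }
  }
  emit <- function(a) {
    s <- paste0(atom_qtoken(q, a), paste(ring_tok[[a]], collapse = ""))
    kids <- children[[a]]
    for (ii in seq_along(kids)) {
      nb <- kids[ii]
      sub <- paste0(bond_qtoken(q$bexprs[[bond_at(a, nb)]]), emit(nb))
      s <- paste0(s, if (ii < length(kids)) paste0("(", sub, ")") else sub)
    }
    s
  }
  comps <- character()
  groups <- integer()
  for (a in seq_len(nq)) {
    if (visited[a]) next
    walk(a)
    comps <- c(comps, emit(a))
    groups <- c(groups, q$comp[a])
  }
  parts <- vapply(seq_along(comps), function(i)
    if (groups[i] > 0L) paste0("(", comps[i], ")") else comps[i], character(1))
  paste(parts, collapse = ".")
}

atom_qtoken <- function(q, a) {
  e <- q$atoms[[a]]
  body <- normalize_expression(e, "atom")
  map <- q$maps[a]
  if (e$op == "leaf" && e$prim == "any" && map == 0L) return("*")
  paste0("[", body, if (map > 0L) paste0(":", map), "]")
}

bond_qtoken <- function(e) {
  if (e$op == "leaf" && e$prim == "default") return("")
  normalize_expression(e, "bond")
}
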