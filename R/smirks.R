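#' Parse a SMIRKS reaction
#'
#' Splits a SMIRKS string into its `reactants > agents > products` sides,
#' parses each side as SMARTS, pairs reactant and product atoms by equal map
#' indices, runs the mapping/consistency validation and, when the reaction
#' is valid, compiles the transformation plan (atom/bond/stereo
#' instructions). Map index 0 and unindexed atoms both count as unmapped.
#'
#' @param text a SMIRKS string containing exactly two top-level `>`
#'   separators (`>>` for empty agents).
#' @return An object of class `smirks_reaction` with fields `reactant`,
#'   `agent`, `product` (query molecules), `pairs` (data frame `map`,
#'   `ridx`, `pidx`), `unmapped_reactant`, `unmapped_product`, `report`
#'   (see [validate_smirks]) and `plan` (`NULL` when validation failed).
#' @export
#' @examples
#' rxn <- parse_smirks("[C:1]=[C:2]>>[C:1][C:2]")
#' rxn$report$errors   # empty: valid
parse_smirks <- function(text) {
  parts <- split_smirks(text)
  reactant <- parse_smarts(parts[1])
  agent <- if (nzchar(parts[2])) parse_smarts(parts[2]) else parse_smarts("")
  product <- parse_smarts(parts[3])
  rmap <- reactant$maps; pmap <- product$maps
  common <- intersect(rmap[rmap > 0L], pmap[pmap > 0L])
  pairs <- data.frame(map = sort(common))
  pairs$ridx <- match(pairs$map, rmap)
  pairs$pidx <- match(pairs$map, pmap)
  rxn <- structure(list(
    reactant = reactant, agent = agent, product = product,
    pairs = pairs,
    unmapped_reactant = which(!(rmap > 0L & rmap %in% common)),
    unmapped_product = which(!(pmap > 0L & pmap %in% common)),
    source_text = text), class = "smirks_reaction")
  rxn$report <- validate_smirks(rxn)
  rxn$plan <- if (length(rxn$report$errors) == 0L) compile_plan(rxn) else NULL
  rxn
}

split_smirks <- function(text) {
  parts <- strsplit(text, ">", fixed = TRUE)[[1]]
  if (substr(text, nchar(text), nchar(text)) == ">") parts <- c(parts, "")
  if (length(parts) != 3L)
    stop("SMIRKS must have exactly two '>' separators (reactants>agents>products)")
  parts
}

#' @export
print.smirks_reaction <- function(x, ...) {
  ok <- length(x$report$errors) == 0L
  cat(sprintf("<smirks reaction%s> %s\n",
              if (ok) "" else sprintf(" [%d validation error(s)]",
                                      length(x$report$errors)),
              x$source_text))
  invisible(x)
}

#' Validate the atom mapping of a SMIRKS reaction
#'
#' Implements the mapping sanity rules: a map index present on only one side
#' is `MISSING_MAP`; a repeated index on one side is `REPEATED_MAP`; a
#' mapped pair whose two sides have defined but different elements is
#' `ELEMENT_MISMATCH` (both sides undefined is allowed); an unmapped product
#' atom with undefined element is `UNMAPPED_PRODUCT_UNDEFINED_ELEMENT`
#' (unmapped reactant atoms may be undefined); a product bond with undefined
#' order is `PRODUCT_BOND_ORDER_UNDEFINED` unless it joins two mapped atoms
#' and the corresponding reactant bond carries the identical (normalized)
#' expression. A pair with a defined element on one side only is allowed;
#' the defined side governs matching.
#'
#' @param rxn a [parse_smirks] reaction (called automatically by it).
#' @return A list with `errors`: a list of `list(code, message, fragment)`.
#' @export
validate_smirks <- function(rxn) {
  errors <- list()
  add <- function(code, message, fragment = "") {
    errors[[length(errors) + 1L]] <<- list(code = code, message = message,
                                           fragment = fragment)
  }
  rmap <- rxn$reactant$maps; pmap <- rxn$product$maps
  for (side in list(list(m = rmap, name = "reactant"),
                    list(m = pmap, name = "product"))) {
    mm <- side$m[side$m > 0L]
    for (d in unique(mm[duplicated(mm)]))
      add("REPEATED_MAP", sprintf("map index %d repeated on the %s side", d, side$name),
          as.character(d))
  }
  only_r <- setdiff(rmap[rmap > 0L], pmap[pmap > 0L])
  only_p <- setdiff(pmap[pmap > 0L], rmap[rmap > 0L])
  for (d in only_r)
    add("MISSING_MAP", sprintf("map index %d missing on the product side", d), as.character(d))
  for (d in only_p)
    add("MISSING_MAP", sprintf("map index %d missing on the reactant side", d), as.character(d))
  for (i in seq_len(nrow(rxn$pairs))) {
    re <- extract_element(rxn$reactant$atoms[[rxn$pairs$ridx[i]]])
    pe <- extract_element(rxn$product$atoms[[rxn$pairs$pidx[i]]])
    if (!is.na(re) && !is.na(pe) && re != pe)
      add("ELEMENT_MISMATCH",
          sprintf("mapped pair %d: reactant element %s vs product element %s",
                  rxn$pairs$map[i], re, pe), as.character(rxn$pairs$map[i]))
  }
  for (p in rxn$unmapped_product) {
    if (is.na(extract_element(rxn$product$atoms[[p]])))
      add("UNMAPPED_PRODUCT_UNDEFINED_ELEMENT",
          sprintf("unmapped product atom %d has undefined element", p),
          normalize_expression(rxn$product$atoms[[p]]))
  }
  # product bonds with undefined order
  pb <- rxn$product$bonds
  for (k in seq_len(nrow(pb))) {
    if (!is.na(extract_bond_order(rxn$product$bexprs[[k]]))) next
    p1 <- pb$a1[k]; p2 <- pb$a2[k]
    ok <- FALSE
    if (p1 %in% rxn$pairs$pidx && p2 %in% rxn$pairs$pidx) {
      r1 <- rxn$pairs$ridx[match(p1, rxn$pairs$pidx)]
      r2 <- rxn$pairs$ridx[match(p2, rxn$pairs$pidx)]
      rk <- query_bond_index(rxn$reactant, r1, r2)
      if (!is.na(rk)) {
        same <- identical(normalize_expression(rxn$reactant$bexprs[[rk]], "bond"),
                          normalize_expression(rxn$product$bexprs[[k]], "bond"))
        ok <- same
      }
    }
    if (!ok)
      add("PRODUCT_BOND_ORDER_UNDEFINED",
          sprintf("product bond %d-%d has undefined bond order", p1, p2),
          normalize_expression(rxn$product$bexprs[[k]], "bond"))
  }
  list(errors = errors)
}

query_bond_index <- function(q, a, b) {
  k <- which((q$bonds$a1 == a & q$bonds$a2 == b) | (q$bonds$a1 == b & q$bonds$a2 == a))
  if (length(k)) k[1] else NA_integer_
}

#' Compile a validated SMIRKS reaction into a transformation plan
#'
#' The plan lists the graph edits implied by side-by-side comparison of the
#' two sides: deletions (unmapped reactant atoms, with their incident
#' bonds), creations (unmapped product atoms; hydrogen counts are
#' recomputed from the valence model when the expression does not pin
#' them), atom property updates for mapped pairs (charge, total hydrogen
#' count, aromatic flag — each emitted only when the product side pins a
#' unique value that is not already pinned identically on the reactant
#' side), bond deletions/creations/order updates, and stereo instructions
#' from `@`/`@@` and directional primitives (create when product-only,
#' remove when reactant-only, update when both).
#'
#' @param rxn a validated [parse_smirks] reaction.
#' @return A list of instruction sets (class `transform_plan`).
#' @export
compile_plan <- function(rxn) {
  pairs <- rxn$pairs
  ridx_of_p <- function(p) pairs$ridx[match(p, pairs$pidx)]
  creations <- list()
  creation_of_p <- integer(0)
  for (p in rxn$unmapped_product) {
    props <- extract_properties(rxn$product$atoms[[p]])
    creations[[length(creations) + 1L]] <- list(
      pidx = p,
      element = props$element,
      charge = if (is.na(props$charge)) 0L else props$charge,
      nH = props$total_H,                 # NA: recompute from valence model
      aromatic = isTRUE(props$aromatic))
    creation_of_p[as.character(p)] <- length(creations)
  }
  pref <- function(p) {
    # reference to a product atom: mapped reactant atom or created atom
    if (p %in% pairs$pidx) list(kind = "mapped", ridx = ridx_of_p(p))
    else list(kind = "new", cidx = creation_of_p[[as.character(p)]])
  }

  charge_updates <- list(); h_updates <- list(); arom_updates <- list()
  for (i in seq_len(nrow(pairs))) {
    rex <- rxn$reactant$atoms[[pairs$ridx[i]]]
    pex <- rxn$product$atoms[[pairs$pidx[i]]]
    rp <- extract_properties(rex); pp <- extract_properties(pex)
    # a product bracket atom without any charge primitive is neutral; that
    # only registers as a change when the reactant side constrains charge
    pcharge <- pp$charge
    if (is.na(pcharge) && !expression_mentions(pex, "charge") &&
        expression_mentions(rex, "charge"))
      pcharge <- 0L
    if (!is.na(pcharge) && (is.na(rp$charge) || rp$charge != pcharge))
      charge_updates[[length(charge_updates) + 1L]] <-
        list(ridx = pairs$ridx[i], value = pcharge)
    if (!is.na(pp$total_H) && (is.na(rp$total_H) || rp$total_H != pp$total_H))
      h_updates[[length(h_updates) + 1L]] <-
        list(ridx = pairs$ridx[i], value = pp$total_H)
    if (is.na(pp$total_H) && expression_mentions(pex, "totalH") &&
        !identical(normalize_expression(pex), normalize_expression(rex)))
      warning(sprintf("ambiguous product H specification for map %d; no H update compiled",
                      pairs$map[i]), call. = FALSE)
    if (!is.na(pp$aromatic) && (is.na(rp$aromatic) || rp$aromatic != pp$aromatic))
      arom_updates[[length(arom_updates) + 1L]] <-
        list(ridx = pairs$ridx[i], value = pp$aromatic)
  }

  bond_deletions <- list(); bond_creations <- list(); bond_updates <- list()
  # reactant bonds between mapped atoms that vanish on the product side
  rb <- rxn$reactant$bonds
  for (k in seq_len(nrow(rb))) {
    r1 <- rb$a1[k]; r2 <- rb$a2[k]
    if (!(r1 %in% pairs$ridx && r2 %in% pairs$ridx)) next
    p1 <- pairs$pidx[match(r1, pairs$ridx)]
    p2 <- pairs$pidx[match(r2, pairs$ridx)]
    if (is.na(query_bond_index(rxn$product, p1, p2)))
      bond_deletions[[length(bond_deletions) + 1L]] <- list(r1 = r1, r2 = r2)
  }
  pb <- rxn$product$bonds
  for (k in seq_len(nrow(pb))) {
    p1 <- pb$a1[k]; p2 <- pb$a2[k]
    po <- extract_bond_order(rxn$product$bexprs[[k]])
    both_mapped <- p1 %in% pairs$pidx && p2 %in% pairs$pidx
    if (both_mapped) {
      r1 <- ridx_of_p(p1); r2 <- ridx_of_p(p2)
      rk <- query_bond_index(rxn$reactant, r1, r2)
      if (is.na(rk)) {
        bond_creations[[length(bond_creations) + 1L]] <-
          list(i = pref(p1), j = pref(p2), order = po)
      } else if (!is.na(po)) {
        ro <- extract_bond_order(rxn$reactant$bexprs[[rk]])
        if (is.na(ro) || !identical(ro, po))
          bond_updates[[length(bond_updates) + 1L]] <-
            list(r1 = r1, r2 = r2, order = po)
      }
    } else {
      bond_creations[[length(bond_creations) + 1L]] <-
        list(i = pref(p1), j = pref(p2), order = po)
    }
  }

  stereo <- compile_stereo_instructions(rxn, pairs, pref)

  structure(list(
    deletions = rxn$unmapped_reactant,
    creations = creations,
    charge_updates = charge_updates,
    h_updates = h_updates,
    arom_updates = arom_updates,
    bond_deletions = bond_deletions,
    bond_creations = bond_creations,
    bond_order_updates = bond_updates,
    stereo = stereo), class = "transform_plan")
}

expression_mentions <- function(e, prim) {
  switch(e$op,
    leaf = e$prim == prim,
    not = expression_mentions(e$arg, prim),
    any(vapply(e$args, expression_mentions, logical(1), prim)))
}

## Tetrahedral and cis/trans instructions from chirality and directional
## primitives on the two sides.
compile_stereo_instructions <- function(rxn, pairs, pref) {
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    rch <- extract_chirality(rxn$reactant$atoms[[pairs$ridx[i]]])
    pch <- extract_chirality(rxn$product$atoms[[pairs$pidx[i]]])
    if (pch == 0L && rch == 0L) next
    if (pch == 0L) {
      out[[length(out) + 1L]] <- list(action = "remove", kind = "tetrahedral",
                                      ridx = pairs$ridx[i])
      next
    }
    qlig <- query_ligand_order(rxn$product, pairs$pidx[i])
    if (length(qlig) != 4L) {
      warning("product chirality with fewer than 4 ligands ignored", call. = FALSE)
      next
    }
    refs <- lapply(qlig, function(p) if (p == 0L) list(kind = "placeholder") else pref(p))
    out[[length(out) + 1L]] <- list(
      action = if (rch == 0L) "create" else "update",
      kind = "tetrahedral", ridx = pairs$ridx[i],
      parity = pch, ligands = refs)
  }
  # cis/trans: double bonds in the product flanked by directional bonds
  ct <- side_cistrans(rxn$product)
  for (el in ct) {
    out[[length(out) + 1L]] <- list(
      action = "set", kind = "cistrans",
      atoms = lapply(el$atoms, pref), refs = lapply(el$refs, pref),
      config = el$config)
  }
  # reactant-only cis/trans marks mean removal when the product has none
  rct <- side_cistrans(rxn$reactant)
  pmapid <- function(p) rxn$product$maps[p]
  rmapid <- function(r) rxn$reactant$maps[r]
  pct_keys <- lapply(ct, function(el) sort(pmapid(el$atoms)))
  for (el in rct) {
    key <- sort(rmapid(el$atoms))
    if (any(key == 0L)) next
    if (!any(vapply(pct_keys, identical, logical(1), key)))
      out[[length(out) + 1L]] <- list(action = "remove_cistrans",
                                      atoms = el$atoms)
  }
  out
}

## Cis/trans descriptors written on one SMIRKS side, in query-atom indices.
side_cistrans <- function(q) {
  res <- list()
  if (!length(q$bexprs)) return(res)
  is_dir <- vapply(q$bexprs, function(e) e$op == "leaf" && e$prim %in% c("dirup", "dirdown"),
                   logical(1))
  orders <- vapply(q$bexprs, function(e) {
    o <- extract_bond_order(e); if (identical(o, 2)) 2L else 0L
  }, integer(1))
  if (!any(is_dir)) return(res)
  for (k in which(orders == 2L)) {
    a <- q$bonds$a1[k]; b <- q$bonds$a2[k]
    da <- q_dir_sign(q, is_dir, a, toward = TRUE)
    db <- q_dir_sign(q, is_dir, b, toward = FALSE)
    if (is.null(da) || is.null(db)) next
    res[[length(res) + 1L]] <- list(
      atoms = c(a, b), refs = c(da$nb, db$nb),
      config = if (da$sign == db$sign) "opposite" else "together")
  }
  res
}

q_dir_sign <- function(q, is_dir, end, toward) {
  for (k in which(is_dir)) {
    a1 <- q$bonds$a1[k]; a2 <- q$bonds$a2[k]
    if (a1 != end && a2 != end) next
    nb <- if (a1 == end) a2 else a1
    s <- if (q$bexprs[[k]]$prim == "dirup") 1L else -1L
    written_to_end <- q$bond_from[k] == nb
    if (toward) { if (!written_to_end) s <- -s } else { if (written_to_end) s <- -s }
    return(list(nb = nb, sign = s))
  }
  NULL
}
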