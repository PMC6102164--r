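#' Transformation configuration
#'
#' The behaviour flags controlling reaction application, with their standard
#' defaults. `ss_mode` selects how the matched sites are combined by
#' [apply_in_place]; the `clear_*`/`add_*`/`check_*`/`convert_*` flags drive
#' product post-processing (only active when `process_result_structures` is
#' `TRUE`); `h_atoms_transformation` turns hydrogen-count primitives in the
#' SMIRKS into edit instructions (mode `IMPLICIT` edits implicit counts,
#' `EXPLICIT` adds/removes explicit H atoms); `apply_stereo_transformation`
#' enables stereo instructions and ligand re-pointing;
#' `check_result_stereo` re-validates surviving stereo elements;
#' `aromaticity_transformation` imposes product-side aromatic flags.
#'
#' @param ss_mode substructure search mode (see [filter_mode]).
#' @param check_result_stereo,filter_equivalent_mappings,process_result_structures,clear_hybridization_before,clear_aromaticity_before,clear_implicit_h_before,clear_explicit_h_before,add_implicit_h_on_process,convert_added_implicit_to_explicit,check_aromaticity_on_process,convert_explicit_to_implicit_on_process,apply_stereo_transformation,h_atoms_transformation,aromaticity_transformation logical flags.
#' @param h_atoms_transformation_mode `"IMPLICIT"` or `"EXPLICIT"`.
#' @return A list of class `transform_config`.
#' @export
transform_config <- function(ss_mode = "NON_OVERLAPPING",
                             check_result_stereo = TRUE,
                             filter_equivalent_mappings = FALSE,
                             process_result_structures = FALSE,
                             clear_hybridization_before = TRUE,
                             clear_aromaticity_before = TRUE,
                             clear_implicit_h_before = TRUE,
                             clear_explicit_h_before = FALSE,
                             add_implicit_h_on_process = FALSE,
                             convert_added_implicit_to_explicit = FALSE,
                             check_aromaticity_on_process = TRUE,
                             convert_explicit_to_implicit_on_process = FALSE,
                             apply_stereo_transformation = FALSE,
                             h_atoms_transformation = FALSE,
                             h_atoms_transformation_mode = c("IMPLICIT", "EXPLICIT"),
                             aromaticity_transformation = FALSE) {
  ss_mode <- match.arg(ss_mode, c("NON_OVERLAPPING", "SINGLE", "NON_IDENTICAL",
                                  "NON_EQUIVALENT", "ALL", "NON_IDENTICAL_FIRST"))
  structure(list(
    ss_mode = ss_mode,
    check_result_stereo = check_result_stereo,
    filter_equivalent_mappings = filter_equivalent_mappings,
    process_result_structures = process_result_structures,
    clear_hybridization_before = clear_hybridization_before,
    clear_aromaticity_before = clear_aromaticity_before,
    clear_implicit_h_before = clear_implicit_h_before,
    clear_explicit_h_before = clear_explicit_h_before,
    add_implicit_h_on_process = add_implicit_h_on_process,
    convert_added_implicit_to_explicit = convert_added_implicit_to_explicit,
    check_aromaticity_on_process = check_aromaticity_on_process,
    convert_explicit_to_implicit_on_process = convert_explicit_to_implicit_on_process,
    apply_stereo_transformation = apply_stereo_transformation,
    h_atoms_transformation = h_atoms_transformation,
    h_atoms_transformation_mode = match.arg(h_atoms_transformation_mode),
    aromaticity_transformation = aromaticity_transformation),
    class = "transform_config")
}

## Site selection shared by the application entry points.
select_sites <- function(rxn, target, config, ctx = NULL) {
  if (is.null(rxn$plan)) stop("reaction failed validation; see $report")
  if (is.null(ctx)) ctx <- match_context(target)
  matches <- enumerate_matches(rxn$reactant, ctx)
  eq <- NULL
  if (config$ss_mode == "NON_EQUIVALENT" || config$filter_equivalent_mappings)
    eq <- equivalence_classes(target)
  matches <- filter_mode(matches, config$ss_mode, equivalence = eq)
  if (config$filter_equivalent_mappings && config$ss_mode != "NON_EQUIVALENT")
    matches <- filter_mode(matches, "NON_EQUIVALENT", equivalence = eq)
  matches
}

#' Apply a reaction directly on the target molecule
#'
#' Finds reaction sites, filters them by the configured search mode, and
#' executes the transformation plan simultaneously at all retained sites on
#' the target itself. Chemically impossible combined results (for instance
#' over-valent atoms when overlapping sites are retained in `ALL` mode) are
#' not prevented; checking product sanity is the caller's responsibility.
#' Overlapping sites whose edits would delete an atom another site still
#' needs raise an application-conflict error.
#'
#' @param rxn a validated [parse_smirks] reaction.
#' @param target a configured [molecule].
#' @param config a [transform_config].
#' @return A list with `modified` (logical) and `molecule` (the transformed
#'   container, possibly fragmented; unchanged when no site matched).
#' @export
apply_in_place <- function(rxn, target, config = transform_config()) {
  sites <- select_sites(rxn, target, config)
  if (!length(sites)) return(list(modified = FALSE, molecule = target))
  out <- execute_plan_sites(rxn$plan, target, sites, config)
  list(modified = TRUE, molecule = out)
}

#' Apply a reaction with one product copy per site
#'
#' Each retained site yields an independent product container (the
#' transformation is applied to a copy at that single site). With
#' `filter_equivalent_mappings` only one representative per class of
#' topologically equivalent sites is kept. Products are post-processed
#' according to the configuration.
#'
#' @inheritParams apply_in_place
#' @return An `application_result`: list with `products` (list of
#'   molecules), `sites` (the match used for each product) and `applied`.
#' @export
apply_with_copies <- function(rxn, target, config = transform_config()) {
  sites <- select_sites(rxn, target, config)
  products <- vector("list", length(sites))
  for (i in seq_along(sites)) {
    p <- execute_plan_sites(rxn$plan, target, sites[i], config)
    products[[i]] <- post_process(p, config)
  }
  structure(list(products = products, sites = sites,
                 applied = length(sites) > 0L),
            class = "application_result")
}

#' Apply a reaction at externally supplied sites
#'
#' Each site is re-verified against the current target before use (atom
#' expressions and bond expressions are re-evaluated on the mapped atoms);
#' stale or invalid sites are rejected per-site and reported, not fatal.
#'
#' @inheritParams apply_in_place
#' @param sites list of matches (as returned by [find_matches]).
#' @return An `application_result` with an extra `rejected` index vector.
#' @export
apply_at_sites <- function(rxn, target, sites, config = transform_config()) {
  if (is.null(rxn$plan)) stop("reaction failed validation; see $report")
  ctx <- match_context(target)
  ok <- vapply(sites, function(s) verify_site(rxn$reactant, ctx, s), logical(1))
  if (any(!ok))
    message(sprintf("%d site(s) failed re-verification and were rejected", sum(!ok)))
  kept <- sites[ok]
  products <- vector("list", length(kept))
  for (i in seq_along(kept)) {
    p <- execute_plan_sites(rxn$plan, target, kept[i], config)
    products[[i]] <- post_process(p, config)
  }
  structure(list(products = products, sites = kept,
                 applied = length(kept) > 0L, rejected = which(!ok)),
            class = "application_result")
}

verify_site <- function(query, ctx, site) {
  m <- site$pairs
  nq <- n_query_atoms(query)
  if (length(m) != nq || anyDuplicated(m[!is.na(m)])) return(FALSE)
  if (any(is.na(m)) || any(m < 1L) || any(m > n_atoms(ctx$mol))) return(FALSE)
  for (qi in seq_len(nq))
    if (!eval_aexpr(query$atoms[[qi]], ctx, m[qi])) return(FALSE)
  for (k in seq_len(nrow(query$bonds))) {
    tb <- mol_bond_between(ctx$mol, m[query$bonds$a1[k]], m[query$bonds$a2[k]])
    if (tb == 0L || !eval_bexpr(query$bexprs[[k]], ctx, tb)) return(FALSE)
  }
  TRUE
}

#' Execute a transformation plan at one site
#'
#' Low-level single-site application; [apply_with_copies] and
#' [apply_in_place] are the usual entry points. The fixed order of
#' operations is: bond deletions, atom deletions, atom property updates,
#' atom creations, bond creations and order updates, hydrogen-count
#' adjustments (only when `h_atoms_transformation` is set), then stereo
#' instructions.
#'
#' @param plan a [compile_plan] result.
#' @param target a [molecule].
#' @param site one match.
#' @param config a [transform_config].
#' @return The modified molecule.
#' @export
execute_plan_at_site <- function(plan, target, site, config = transform_config()) {
  execute_plan_sites(plan, target, list(site), config)
}

## Core editor: applies the plan at each site with stable atom indices
## (atom removals are deferred to a single final pass).
execute_plan_sites <- function(plan, mol, sites, config) {
  to_delete <- integer(0)
  touched <- integer(0)           # atoms whose bonding changed
  replacements <- list()          # focus -> newly attached atom (for stereo)
  stereo_new <- list()            # stereo elements from SMIRKS instructions
  stereo_drop_focus <- integer(0)
  stereo_drop_ct <- list()
  orig_stereo <- mol$stereo

  for (site in sites) {
    m <- site$pairs
    tgt <- function(r) m[r]
    # conflict with deletions from an earlier site
    if (any(m %in% to_delete))
      stop("application conflict: a site references an atom deleted by another site")

    # 1. bond deletions between mapped atoms
    for (bd in plan$bond_deletions) {
      k <- mol_bond_between(mol, tgt(bd$r1), tgt(bd$r2))
      if (k > 0L) {
        touched <- c(touched, mol$bonds$a1[k], mol$bonds$a2[k])
        mol$bonds <- mol$bonds[-k, , drop = FALSE]
      }
    }
    # 2. atom deletions (deferred): incident bonds vanish with the atom
    del <- vapply(plan$deletions, tgt, integer(1))
    if (length(del)) {
      nbs <- unlist(lapply(del, function(a) {
        b <- mol$bonds
        c(b$a2[b$a1 == a], b$a1[b$a2 == a])
      }))
      touched <- c(touched, nbs)
      to_delete <- c(to_delete, del)
    }
    # 3. atom property updates
    for (u in plan$charge_updates) mol$atoms$charge[tgt(u$ridx)] <- u$value
    if (config$aromaticity_transformation)
      for (u in plan$arom_updates) mol$atoms$aromatic[tgt(u$ridx)] <- u$value
    # 4. atom creations
    created <- integer(length(plan$creations))
    for (ci in seq_along(plan$creations)) {
      cr <- plan$creations[[ci]]
      mol$atoms <- rbind(mol$atoms, new_atom_row(
        cr$element, charge = cr$charge,
        nH = if (is.na(cr$nH)) 0L else cr$nH, aromatic = cr$aromatic))
      created[ci] <- nrow(mol$atoms)
    }
    resolve_ref <- function(ref) {
      switch(ref$kind,
        mapped = tgt(ref$ridx),
        new = created[ref$cidx],
        placeholder = 0L)
    }
    # 5. bond creations and order updates
    for (bc in plan$bond_creations) {
      i <- resolve_ref(bc$i); j <- resolve_ref(bc$j)
      if (mol_bond_between(mol, i, j) > 0L) next
      ord <- bc$order
      arom <- identical(ord, "ar")
      mol$bonds <- rbind(mol$bonds, data.frame(
        a1 = min(i, j), a2 = max(i, j),
        order = if (arom) 1L else as.integer(ord), aromatic = arom,
        stringsAsFactors = FALSE))
      touched <- c(touched, i, j)
      for (x in c(i, j)) {
        key <- as.character(x)
        replacements[[key]] <- c(replacements[[key]], if (x == i) j else i)
      }
    }
    for (bu in plan$bond_order_updates) {
      k <- mol_bond_between(mol, tgt(bu$r1), tgt(bu$r2))
      if (k == 0L) next
      mol$bonds$order[k] <- if (identical(bu$order, "ar")) 1L else as.integer(bu$order)
      mol$bonds$aromatic[k] <- identical(bu$order, "ar")
      touched <- c(touched, mol$bonds$a1[k], mol$bonds$a2[k])
    }
    # recompute implicit H for creations that did not pin a hydrogen count
    bos <- mol_bond_order_sum(mol)
    for (ci in seq_along(plan$creations)) {
      cr <- plan$creations[[ci]]
      if (is.na(cr$nH))
        mol$atoms$nH[created[ci]] <- implicit_h_for(cr$element, cr$charge, bos[created[ci]])
    }
    # 6. hydrogen-count adjustments on mapped atoms
    if (config$h_atoms_transformation) {
      for (u in plan$h_updates)
        mol <- set_total_h(mol, tgt(u$ridx), u$value, config$h_atoms_transformation_mode)
    }
    # 7. stereo instructions (collected; applied after all sites)
    if (config$apply_stereo_transformation) {
      for (si in plan$stereo) {
        if (si$action == "remove") {
          stereo_drop_focus <- c(stereo_drop_focus, tgt(si$ridx))
        } else if (si$action == "remove_cistrans") {
          stereo_drop_ct[[length(stereo_drop_ct) + 1L]] <-
            sort(vapply(si$atoms, tgt, integer(1)))
        } else if (si$kind == "tetrahedral") {
          lig <- vapply(si$ligands, resolve_ref, integer(1))
          stereo_new[[length(stereo_new) + 1L]] <- list(
            type = "tetrahedral", focus = tgt(si$ridx),
            ligands = lig, parity = si$parity)
        } else if (si$kind == "cistrans") {
          stereo_new[[length(stereo_new) + 1L]] <- list(
            type = "cistrans",
            atoms = vapply(si$atoms, resolve_ref, integer(1)),
            refs = vapply(si$refs, resolve_ref, integer(1)),
            config = si$config)
        }
      }
    }
  }

  mol$stereo <- transform_stereo(mol, orig_stereo, to_delete, touched,
                                 replacements, stereo_new,
                                 stereo_drop_focus, stereo_drop_ct, config)
  mol <- mol_remove_atoms(mol, to_delete)
  if (config$check_result_stereo) mol$stereo <- validate_stereo(mol)
  mol
}

## Carry the pre-edit stereo list through the graph edits.
transform_stereo <- function(mol, orig, deleted, touched, replacements,
                             stereo_new, drop_focus, drop_ct, config) {
  touched <- unique(touched)
  out <- list()
  new_focus <- vapply(stereo_new, function(se)
    if (se$type %in% c("tetrahedral", "allene")) se$focus else NA_integer_,
    integer(1))
  new_ct <- lapply(stereo_new, function(se)
    if (se$type == "cistrans") sort(se$atoms) else NULL)
  for (se in orig) {
    if (se$type %in% c("tetrahedral", "allene")) {
      f <- se$focus
      if (f %in% deleted || f %in% drop_focus || f %in% new_focus) next
      gone <- se$ligands > 0L & se$ligands %in% deleted
      if (any(gone)) {
        if (!config$apply_stereo_transformation) next
        # re-point a single replaced ligand to the atom newly bonded here
        cand <- setdiff(replacements[[as.character(f)]], se$ligands)
        if (sum(gone) != 1L || length(cand) != 1L) next
        se$ligands[gone] <- cand
      } else if (!config$apply_stereo_transformation && f %in% touched) {
        next   # directly influenced and no stereo transformation requested
      }
      out[[length(out) + 1L]] <- se
    } else {
      key <- sort(se$atoms)
      if (any(c(se$atoms, se$refs) %in% deleted)) next
      if (any(vapply(drop_ct, identical, logical(1), key))) next
      if (any(vapply(new_ct, function(k) !is.null(k) && identical(k, key), logical(1)))) next
      if (!config$apply_stereo_transformation &&
          any(c(se$atoms, se$refs) %in% touched)) next
      out[[length(out) + 1L]] <- se
    }
  }
  c(out, stereo_new)
}

## Drop stereo elements that are no longer geometrically meaningful:
## tetrahedral centres need four distinct, live, pairwise non-equivalent
## ligands (one implicit-H placeholder allowed); cis/trans elements need a
## live double bond with one reference neighbour on each end.
validate_stereo <- function(mol) {
  eq <- NULL
  keep <- list()
  for (se in mol$stereo) {
    if (se$type %in% c("tetrahedral", "allene")) {
      lig <- se$ligands
      if (length(lig) != 4L) next
      if (sum(lig == 0L) > 1L) next
      if (sum(lig == 0L) == 1L && mol$atoms$nH[se$focus] != 1L) next
      real <- lig[lig > 0L]
      if (anyDuplicated(real)) next
      if (any(real > n_atoms(mol))) next
      if (se$type == "tetrahedral") {
        ok <- all(vapply(real, function(x) mol_bond_between(mol, se$focus, x) > 0L,
                         logical(1)))
        if (!ok) next
        if (mol_degree(mol)[se$focus] + mol$atoms$nH[se$focus] != 4L) next
      }
      if (is.null(eq)) eq <- equivalence_classes(mol)
      cls <- c(eq[real], if (any(lig == 0L)) -1L)
      if (anyDuplicated(cls)) next
      keep[[length(keep) + 1L]] <- se
    } else {
      k <- mol_bond_between(mol, se$atoms[1], se$atoms[2])
      if (k == 0L || mol$bonds$order[k] != 2L || mol$bonds$aromatic[k]) next
      if (mol_bond_between(mol, se$atoms[1], se$refs[1]) == 0L) next
      if (mol_bond_between(mol, se$atoms[2], se$refs[2]) == 0L) next
      keep[[length(keep) + 1L]] <- se
    }
  }
  keep
}

## Set the total hydrogen count of one atom.
set_total_h <- function(mol, a, value, mode) {
  expl <- mol_explicit_h(mol)[a]
  if (mode == "IMPLICIT") {
    newn <- value - expl
    if (newn < 0L)
      stop(sprintf("hydrogen transformation would give atom %d a negative implicit H count", a))
    mol$atoms$nH[a] <- as.integer(newn)
    return(mol)
  }
  # EXPLICIT: add or remove explicit H atoms adjacent to `a`
  total <- mol$atoms$nH[a] + expl
  delta <- value - total
  if (delta > 0L) {
    for (k in seq_len(delta)) {
      mol$atoms <- rbind(mol$atoms, new_atom_row("H"))
      h <- nrow(mol$atoms)
      mol$bonds <- rbind(mol$bonds, data.frame(
        a1 = min(a, h), a2 = max(a, h), order = 1L, aromatic = FALSE,
        stringsAsFactors = FALSE))
    }
  } else if (delta < 0L) {
    need <- -delta
    adjh <- which(mol$atoms$element == "H" & (
      vapply(seq_len(n_atoms(mol)), function(x) mol_bond_between(mol, a, x) > 0L, logical(1))))
    drop <- utils::head(sort(adjh), need)    # deterministic: lowest indices
    need <- need - length(drop)
    if (need > mol$atoms$nH[a])
      stop(sprintf("hydrogen transformation would give atom %d a negative H count", a))
    mol$atoms$nH[a] <- mol$atoms$nH[a] - need
    mol <- mol_remove_atoms(mol, drop)
  }
  mol
}

#' Post-process a product molecule
#'
#' Runs the configured cleanup pipeline on one product. Nothing happens
#' unless `process_result_structures` is `TRUE`; then, in order: clear
#' aromaticity flags, clear implicit hydrogens, remove explicit hydrogens,
#' add implicit hydrogens from the valence model, convert the hydrogens
#' added in this pass to explicit atoms, re-perceive aromaticity, and fold
#' explicit hydrogens back to implicit — each step gated by its flag.
#'
#' @param product a [molecule].
#' @param config a [transform_config].
#' @return The processed molecule.
#' @export
post_process <- function(product, config = transform_config()) {
  if (!config$process_result_structures) return(product)
  if (config$clear_aromaticity_before) {
    product$atoms$aromatic <- rep(FALSE, n_atoms(product))
    product$bonds$aromatic <- rep(FALSE, n_bonds(product))
  }
  if (config$clear_implicit_h_before) product <- hydrogens(product, "clear_implicit")
  if (config$clear_explicit_h_before) product <- hydrogens(product, "clear_explicit")
  before <- product$atoms$nH
  # re-typing: cleared implicit counts are restored from the valence model
  if (config$clear_implicit_h_before) product <- hydrogens(product, "add_implicit")
  if (config$add_implicit_h_on_process) product <- hydrogens(product, "add_implicit")
  if (config$convert_added_implicit_to_explicit && config$add_implicit_h_on_process) {
    added <- pmax(product$atoms$nH - before, 0L)
    keep_implicit <- product$atoms$nH - added
    product$atoms$nH <- added
    product <- hydrogens(product, "implicit_to_explicit")
    product$atoms$nH[seq_along(keep_implicit)] <- keep_implicit
  }
  if (config$check_aromaticity_on_process) product <- perceive_aromaticity(product)
  if (config$convert_explicit_to_implicit_on_process)
    product <- hydrogens(product, "explicit_to_implicit")
  product
}
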