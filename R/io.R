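#' Read an SDF (MDL molfile V2000) file
#'
#' Reads V2000 connection tables: elements, bond orders, formal charges
#' (both the atom-block charge column and `M  CHG` property lines, the
#' latter taking precedence) and `M  ISO` isotopes. Aromatic bonds (type 4)
#' are kekulized; implicit hydrogens are filled from the valence model and
#' aromaticity is perceived, so the returned molecules are configured.
#' Wedge/hash flags are ignored (no stereo is inferred from 0D input).
#' Malformed records are skipped with a warning. V3000 records are
#' rejected.
#'
#' @param path file path.
#' @return A named list of [molecule] objects (names from the title line).
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(0, utils::head(lines, -1) == "$$$$")))
  out <- list()
  skipped <- 0L
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (!length(rec) || all(!nzchar(trimws(rec)))) next
    m <- tryCatch(parse_molfile(rec), error = function(e) {
      warning("skipping SDF record: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(m)) { skipped <- skipped + 1L; next }
    out[[length(out) + 1L]] <- m$mol
    names(out)[length(out)] <- m$name
  }
  attr(out, "skipped") <- skipped
  out
}

parse_molfile <- function(rec) {
  if (length(rec) < 4L) stop("truncated record")
  name <- trimws(rec[1])
  counts <- rec[4]
  if (grepl("V3000", counts)) stop("V3000 connection tables are not supported")
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) stop("bad counts line")
  if (length(rec) < 4L + na + nb) stop("truncated record")
  atoms <- empty_atoms()
  old_charge <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  for (i in seq_len(na)) {
    ln <- rec[4 + i]
    el <- trimws(substr(ln, 32, 34))
    if (!nzchar(el)) stop("missing element symbol")
    cc <- suppressWarnings(as.integer(substr(ln, 37, 39)))
    ch <- if (!is.na(cc) && as.character(cc) %in% names(old_charge))
      old_charge[[as.character(cc)]] else 0L
    atoms <- rbind(atoms, new_atom_row(el, charge = ch))
  }
  bonds <- empty_bonds()
  arom_flag <- logical(0)
  for (i in seq_len(nb)) {
    ln <- rec[4 + na + i]
    a1 <- as.integer(substr(ln, 1, 3)); a2 <- as.integer(substr(ln, 4, 6))
    bt <- as.integer(substr(ln, 7, 9))
    if (is.na(a1) || is.na(a2) || a1 < 1 || a2 < 1 || a1 > na || a2 > na)
      stop("bad bond line")
    arom <- !is.na(bt) && bt == 4L
    ord <- if (arom || is.na(bt) || bt < 1L || bt > 3L) 1L else bt
    bonds <- rbind(bonds, data.frame(a1 = min(a1, a2), a2 = max(a1, a2),
                                     order = ord, aromatic = arom,
                                     stringsAsFactors = FALSE))
  }
  for (ln in rec[-seq_len(4 + na + nb)]) {
    if (startsWith(ln, "M  CHG")) {
      vals <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
      n <- vals[1]
      for (k in seq_len(n)) atoms$charge[vals[2 * k]] <- vals[2 * k + 1]
    } else if (startsWith(ln, "M  ISO")) {
      vals <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
      n <- vals[1]
      for (k in seq_len(n)) atoms$isotope[vals[2 * k]] <- vals[2 * k + 1]
    } else if (startsWith(ln, "M  END")) break
  }
  if (nrow(bonds)) atoms$aromatic[unique(c(bonds$a1[bonds$aromatic],
                                           bonds$a2[bonds$aromatic]))] <- TRUE
  mol <- molecule(atoms, bonds)
  mol <- kekulize(mol)
  mol <- hydrogens(mol, "add_implicit")
  mol <- perceive_aromaticity(mol)
  list(mol = mol, name = name)
}

#' Write molecules to an SDF (V2000) file
#'
#' Explicit graph only: implicit hydrogens stay implicit (counts are
#' recomputed on reading), coordinates are written as zeros, charges go to
#' `M  CHG` lines and isotopes to `M  ISO`. Aromatic bonds are written with
#' their Kekule order, so any V2000 reader reconstructs the same graph.
#'
#' @param mols a list of [molecule] objects (names become title lines).
#' @param path file path.
#' @return Invisibly, the path.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  nms <- names(mols)
  if (is.null(nms)) nms <- rep("", length(mols))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(mols)) {
    mol <- mols[[i]]
    writeLines(c(nms[i], "  smirkr", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       n_atoms(mol), n_bonds(mol)), con)
    for (a in seq_len(n_atoms(mol)))
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         0, 0, 0, mol$atoms$element[a]), con)
    for (k in seq_len(n_bonds(mol)))
      writeLines(sprintf("%3d%3d%3d  0", mol$bonds$a1[k], mol$bonds$a2[k],
                         mol$bonds$order[k]), con)
    chg <- which(mol$atoms$charge != 0L)
    for (a in chg)
      writeLines(sprintf("M  CHG  1 %3d %3d", a, mol$atoms$charge[a]), con)
    iso <- which(!is.na(mol$atoms$isotope))
    for (a in iso)
      writeLines(sprintf("M  ISO  1 %3d %3d", a, mol$atoms$isotope[a]), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Read a SMILES file
#'
#' One record per line: a SMILES string optionally followed by whitespace
#' and an identifier. Empty lines and `#` comments are skipped; lines that
#' fail to parse are dropped with a warning naming the line number.
#'
#' @param path file path.
#' @return A named list of [molecule] objects; unparsed line numbers in
#'   attribute `"failed"`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); failed <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "\\s+")[[1]]
    id <- if (length(parts) > 1L) parts[2] else sprintf("line%d", i)
    m <- tryCatch(parse_smiles(parts[1]), error = function(e) {
      warning(sprintf("line %d: %s", i, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(m)) { failed <- c(failed, i); next }
    out[[id]] <- m
  }
  attr(out, "failed") <- failed
  out
}

#' Read a SMIRKS rule file
#'
#' Tab- (or whitespace-) separated lines: `name<TAB>smirks`. Every entry is
#' parsed and validated; entries that fail keep their position but are
#' flagged invalid with the reason.
#'
#' @param path file path.
#' @return A list of entries: `name`, `smirks`, `enabled`, `valid`,
#'   `reason` (`""` when valid) and `rxn` (the parsed reaction or `NULL`).
#' @export
read_rule_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) < 2L) parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) < 2L) {
      out[[length(out) + 1L]] <- list(name = ln, smirks = "", enabled = FALSE,
                                      valid = FALSE, reason = "missing SMIRKS column",
                                      rxn = NULL)
      next
    }
    name <- parts[1]; smk <- parts[2]
    rxn <- tryCatch(suppressWarnings(parse_smirks(smk)), error = function(e) e)
    if (inherits(rxn, "error")) {
      out[[length(out) + 1L]] <- list(name = name, smirks = smk, enabled = FALSE,
                                      valid = FALSE, reason = conditionMessage(rxn),
                                      rxn = NULL)
    } else if (length(rxn$report$errors)) {
      codes <- vapply(rxn$report$errors, function(e) e$code, character(1))
      out[[length(out) + 1L]] <- list(name = name, smirks = smk, enabled = FALSE,
                                      valid = FALSE,
                                      reason = paste(codes, collapse = ","),
                                      rxn = rxn)
    } else {
      out[[length(out) + 1L]] <- list(name = name, smirks = smk, enabled = TRUE,
                                      valid = TRUE, reason = "", rxn = rxn)
    }
  }
  out
}

## Flag-file names for configuration serialization.
config_flag_names <- c(
  ss_mode = "FlagSSMode",
  check_result_stereo = "FlagCheckResultStereo",
  filter_equivalent_mappings = "FlagFilterEquivalentMappings",
  process_result_structures = "FlagProcessResultStructures",
  clear_hybridization_before = "FlagClearHybridizationBeforeResultProcess",
  clear_aromaticity_before = "FlagClearAromaticityBeforeResultProcess",
  clear_implicit_h_before = "FlagClearImplicitHAtomsBeforeResultProcess",
  clear_explicit_h_before = "FlagClearExcplicitHAtomsBeforeResultProcess",
  add_implicit_h_on_process = "FlagAddImplicitHAtomsOnResultProcess",
  convert_added_implicit_to_explicit = "FlagConvertAddedImplicitHToExplicitOnResultProcess",
  check_aromaticity_on_process = "FlagCheckAromaticityOnResultProcess",
  convert_explicit_to_implicit_on_process = "FlagConvertExplicitHToImplicitOnResultProcess",
  apply_stereo_transformation = "FlagApplyStereoTransformation",
  h_atoms_transformation = "FlagHAtomsTransformation",
  h_atoms_transformation_mode = "FlagHAtomsTransformationMode",
  aromaticity_transformation = "FlagAromaticityTransformation")

#' Serialize / deserialize a transformation configuration
#'
#' Flat `Flag<Name>=<value>` lines with the conventional flag names (for
#' example `FlagSSMode=SSM_NON_OVERLAPPING`).
#'
#' @param config a [transform_config].
#' @param path file path.
#' @return `write_transform_config` the path, invisibly;
#'   `read_transform_config` a `transform_config`.
#' @export
write_transform_config <- function(config, path) {
  fmt <- function(field) {
    v <- config[[field]]
    if (field == "ss_mode") paste0("SSM_", v)
    else if (is.logical(v)) if (v) "true" else "false"
    else as.character(v)
  }
  writeLines(sprintf("%s=%s", config_flag_names, vapply(names(config_flag_names),
                                                        fmt, character(1))), path)
  invisible(path)
}

#' @rdname write_transform_config
#' @export
read_transform_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  config <- transform_config()
  for (p in kv) {
    key <- trimws(p[1]); val <- trimws(p[2])
    field <- names(config_flag_names)[config_flag_names == key]
    if (!length(field)) stop("unknown configuration flag: ", key)
    config[[field]] <-
      if (field == "ss_mode") sub("^SSM_", "", val)
      else if (field == "h_atoms_transformation_mode") toupper(val)
      else tolower(val) == "true"
  }
  config
}

#' Named example molecules and reactions
#'
#' A deterministic set of molecules (SMILES) and generic reactions (SMIRKS)
#' used throughout the documentation and tests: the diamine/hydroxylation/
#' aromatization examples, the five equivalent spellings of
#' (R)-2-hydroxypropanoic acid, and the standard valid/invalid mapping
#' examples.
#'
#' @return A list with character vectors `molecules`, `reactions` and
#'   `invalid_reactions` (named).
#' @export
fixture_set <- function() {
  molecules <- c(
    methane = "C",
    ethane = "CC",
    ethanol = "CCO",
    propane = "CCC",
    propene = "C=CC",
    cyclohexane = "C1CCCCC1",
    cyclohexene = "C1=CCCCC1",
    benzene = "c1ccccc1",
    pyrrole = "c1cc[nH]c1",
    pyridine = "c1ccncc1",
    dihydropyrrole = "N1CC=CC1",
    ethylpyridine3 = "CCc1cccnc1",
    cyclohexane_12_diamine = "NC1CCCCC1N",
    acetone = "CC(C)=O",
    acetamide = "CC(N)=O",
    n_methylacetamide = "CC(=O)NC",
    lactic_r_1 = "O[C@H](C)C(O)=O",
    lactic_r_2 = "O[C@@H](C(O)=O)C",
    lactic_r_3 = "C[C@@H](O)C(O)=O",
    lactic_r_4 = "C[C@H](C(O)=O)O",
    lactic_r_5 = "C(O)(=O)[C@H](O)C",
    trans_difluoroethene = "F/C=C/F",
    cis_difluoroethene = "F/C=C\\F")
  reactions <- c(
    amide_reduction = "[NX3H0,NX3H1,NX3H2:1][CX3:2]=[OX1]>>[NX3H0,NX3H1,NX3H2:1][CX3:2]([H])[H]",
    dihydropyrrole_aromatization = "[N:1]1[C:2][C:3]=[C:4][C:5]1>>[N:1]1[C:2]=[C:3][C:4]=[C:5]1",
    aromatic_hydroxylation = "[c:1][H]>>[c:1]O[H]",
    aliphatic_hydroxylation_implicit = "[CH3:1]>>[CH2:1][OH]",
    aliphatic_hydroxylation_explicit = "[C:1][H:2]>>[C:1]O[H:2]",
    primary_hydroxylation_explicit = "[CH3:1][H:2]>>[C:1]O[H:2]",
    double_to_single_mapped = "[C:1]=[C:2]>>[C:1][C:2]",
    double_to_single_unmapped = "C=C>>CC",
    double_to_single_mixed = "[C:1]=C>>[C:1]C",
    wildcard_pair_ok = "[C:1][*:2]>>Cl[C:1][*:2]",
    unmapped_halogen_reactant_ok = "[C:1][Cl,Br]>>[C:1]",
    ambiguous_bond_both_sides_ok = "[C:1]-,=[C:2]>>[C:1]-,=[C:2]",
    ambiguous_bond_to_single_ok = "[C:1]-,=[C:2]>>[C:1]-[C:2]")
  invalid_reactions <- c(
    missing_map = "[C:1][C:2]>>[C:1]=[C]",
    repeated_map = "[C:1][C:2]>>[C:1]=[C:1]",
    element_mismatch = "[C:1][C:2]>>[N:1]=[C:2]",
    element_mismatch_o = "[C:1][C:2]>>[O:1][C:2]",
    unmapped_product_undefined = "[C:1]>>[C:1][Cl,Br]",
    undefined_product_bond = "[C:1]=[C:2]>>[C:1]-,=[C:2]",
    undefined_product_bond_new = "[C:1]>>[C:1]-,=C")
  list(molecules = molecules, reactions = reactions,
       invalid_reactions = invalid_reactions)
}

#' Write the fixture set to a directory
#'
#' Emits `molecules.smi` (SMILES file) and `reactions.tsv` /
#' `invalid_reactions.tsv` (rule files); deterministic content across runs.
#'
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- fixture_set()
  writeLines(sprintf("%s %s", fx$molecules, names(fx$molecules)),
             file.path(dir, "molecules.smi"))
  writeLines(sprintf("%s\t%s", names(fx$reactions), fx$reactions),
             file.path(dir, "reactions.tsv"))
  writeLines(sprintf("%s\t%s", names(fx$invalid_reactions), fx$invalid_reactions),
             file.path(dir, "invalid_reactions.tsv"))
  invisible(dir)
}
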