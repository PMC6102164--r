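# Shared oracles, independent of the implementation paths they check.

canon <- function(mol) write_smiles(mol, canonical = TRUE)

# Brute-force substructure enumeration: all injective assignments of query
# atoms to target atoms, checked directly against the expression evaluators.
# O(n^k); only for targets of <= 10 heavy atoms in tests.
brute_force_match_count <- function(query, target) {
  nq <- length(query$atoms)
  nt <- nrow(target$atoms)
  if (nq == 0L || nq > nt) return(0L)
  ctx <- smirkr:::match_context(target)
  perms <- all_injections(nt, nq)
  count <- 0L
  for (p in perms) {
    ok <- TRUE
    for (qi in seq_len(nq)) {
      if (!eval_atom_expression(query$atoms[[qi]], target, p[qi], ctx = ctx)) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    for (k in seq_len(nrow(query$bonds))) {
      bi <- smirkr:::mol_bond_between(target, p[query$bonds$a1[k]], p[query$bonds$a2[k]])
      if (bi == 0L || !eval_bond_expression(query$bexprs[[k]], target, bi, ctx = ctx)) {
        ok <- FALSE; break
      }
    }
    if (ok) count <- count + 1L
  }
  count
}

all_injections <- function(n, k) {
  out <- list()
  pick <- function(chosen) {
    if (length(chosen) == k) { out[[length(out) + 1L]] <<- chosen; return(invisible(NULL)) }
    for (i in setdiff(seq_len(n), chosen)) pick(c(chosen, i))
  }
  pick(integer(0))
  out
}

# Brute-force automorphism orbits by full permutation search (n <= 8).
brute_force_orbits <- function(mol) {
  n <- nrow(mol$atoms)
  key <- paste(mol$atoms$element, mol$atoms$charge, mol$atoms$nH, mol$atoms$aromatic)
  # aromatic bonds compare equal regardless of Kekule order
  bkey <- function(m, i, j) {
    k <- smirkr:::mol_bond_between(m, i, j)
    if (k == 0L) "" else if (m$bonds$aromatic[k]) "ar" else as.character(m$bonds$order[k])
  }
  perms <- asplit(gtools_permutations(n), 1)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in perms) {
    if (any(key[p] != key)) next
    ok <- TRUE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (bkey(mol, i, j) != bkey(mol, p[i], p[j])) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    for (i in seq_len(n)) {
      ri <- find(i); rj <- find(p[i])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# All permutations of 1..n as a matrix (small n only).
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# Hueckel electron count for a single ring, written independently of the
# package's perception code: explicit contributions per atom kind.
huckel_ring_electrons <- function(mol, ring) {
  total <- 0
  for (a in ring) {
    el <- mol$atoms$element[a]
    nbs_dbl <- 0L
    b <- mol$bonds
    for (k in which((b$a1 == a | b$a2 == a) & b$order == 2L))
      nbs_dbl <- nbs_dbl + 1L
    deg <- sum(b$a1 == a | b$a2 == a)
    if (nbs_dbl > 0L) total <- total + 1
    else if (el %in% c("N", "P") && deg + mol$atoms$nH[a] == 3L) total <- total + 2
    else if (el %in% c("O", "S") && deg == 2L) total <- total + 2
    else return(NA)
  }
  total
}
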