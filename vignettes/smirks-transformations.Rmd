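---
title: "Generic reaction transformations with smirkr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generic reaction transformations with smirkr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smirkr)
```

## The problem

A *generic reaction* is a rule that describes the same set of atom and bond
changes across any substrate: "reduce this double bond", "hydroxylate an
aromatic CH", "open this lactone". The SMIRKS linear notation encodes such
rules as two SMARTS patterns — reactants and products — whose atoms are
paired by map indices (`[C:1]=[C:2]>>[C:1][C:2]`). Applying a rule means
(1) finding every embedding of the reactant pattern in a target molecule,
(2) selecting which embeddings (sites) to react, and (3) editing the
molecular graph according to the differences between the two sides.
`smirkr` implements this pipeline end to end in R: SMILES molecules, SMARTS
queries (with recursive environments and component-level grouping), SMIRKS
validation and compilation, site matching in several modes, graph editing
with hydrogen/aromaticity/stereo handling, and reaction searching.

## Data model

A molecule is an attributed undirected graph: atoms carry element, formal
charge, isotope, an *implicit hydrogen count* and an aromatic flag; bonds
carry a Kekulé order (1, 2, 3) and an aromatic flag; a separate list holds
stereo descriptors. Stereochemistry is *relative*: a tetrahedral centre
stores an ordered list of four ligands (a reserved placeholder stands for
an implicit hydrogen) and a binary parity — anticlockwise (`@`) or
clockwise (`@@`) viewed with the first ligand towards the viewer. A
cis/trans element stores the double bond, one reference neighbour on each
end, and whether the references are on the same (`together`) or opposite
sides. No CIP R/S assignment is attempted; equivalent relative spellings of
the same configuration are reconciled by canonicalization, not by absolute
descriptors.

```{r}
m <- parse_smiles("O[C@H](C)C(O)=O")   # (R)-2-hydroxypropanoic acid
m$stereo[[1]]
write_smiles(m, canonical = TRUE)
```

## Numerical and algorithmic choices

**Valence model.** Implicit hydrogens are filled from the Daylight organic
subset: B 3; C 4; N 3,5; O 2; P 3,5; S 2,4,6; halogens 1. Charge shifts the
available valence (+charge for the N/O families, −|charge| for C and B).
Over-valent atoms get zero implicit hydrogens and a warning rather than an
error, since deliberately "incorrect" intermediates are legitimate during
transformation.

**Ring perception.** Rings are perceived as the set of shortest cycles
through each non-bridge edge (deduplicated). On the molecule sizes this
engine targets this coincides with the smallest set of smallest rings for
the usual fused systems, and it is deterministic, which matters more here
than covering exotic cage topologies.

**Aromaticity.** A single documented Hückel model is applied per perceived
ring: one π electron per atom in an endocyclic double bond; two for
pyrrole-type N/P (three connections counting hydrogens) and two-connected
O/S; zero for a carbon whose only double bond is exocyclic
(carbonyl-type); two/zero for ring carbanions/carbocations; any other
contribution disqualifies the ring. A ring is aromatic when the total is
4n+2. The model is intentionally minimal and deterministic; it is not
claimed to reproduce any particular toolkit's model on edge cases (e.g.
azulene, which needs envelope rings, stays non-aromatic here). Aromatic
SMILES input is kekulized on parsing by a backtracking perfect matching
over the atoms that must carry exactly one double bond, so the engine
always holds both Kekulé orders and aromatic flags — transformations edit
orders, perception restores flags.

**Canonical SMILES.** Atom ranks come from iterative invariant refinement
(element, aromaticity, charge, hydrogen count, isotope, degree; neighbour
ranks with Kekulé-independent bond keys), with exhaustive tie-breaking:
every member of the first tied class is promoted in turn and the
lexicographically smallest emitted string wins. This is exponential in
principle but the branching is bounded by symmetry, which is small for
molecules of interest; it buys exact invariance under input atom order and
Kekulé assignment, which the round-trip and identity tests rely on.

**Matching.** Subgraph embedding is a plain backtracking search over a
connectivity-respecting query order, with all-candidates enumeration and a
deterministic result order (sorted target tuples). Chirality primitives are
neutral during candidate screening and re-checked once a full mapping
exists, by comparing the permutation parity of the query's written
neighbour order (mapped onto the target) with the target's stereo element.
Recursive atom expressions re-enter the matcher rooted at the candidate
atom; recursion depth is bounded by the pattern's own nesting.

**Site-selection modes.** `ALL` keeps every embedding, `NON_IDENTICAL`
collapses duplicate atom sets, `NON_EQUIVALENT` keeps one representative
per class of embeddings related by topological equivalence of their target
atoms (equivalence classes are automorphism orbits, computed with the same
matcher), and `SINGLE` keeps the first. For `NON_OVERLAPPING` the design
was genuinely open: a greedy scan in enumeration order can return a
1-element family on inputs whose maximum disjoint family has 2 members
(the diamine example below does exactly that), so the filter computes an
exact maximum disjoint family by branch and bound, preferring
earlier-enumerated matches among ties, with a greedy fallback above 60
matches. Disjointness of the result and determinism are property-tested.

```{r}
d <- parse_smiles("NC1CCCCC1N")
ms <- find_matches(parse_smarts("CCN"), d)
length(ms)
length(filter_mode(ms, "NON_OVERLAPPING"))
length(filter_mode(ms, "NON_EQUIVALENT", equivalence_classes(d)))
```

## Validation and compilation of rules

A SMIRKS is usable only when its mapping passes the sanity rules: no
missing or repeated map indices; mapped pairs may not change a *defined*
element (both-undefined is allowed — the defined side then only governs
matching); unmapped product atoms must have a defined element (they are
created); a product bond may not have an undefined order unless it joins
two mapped atoms with the identical (normalized) expression on the
reactant side. "Identical" is decided on a normalized form — primitives
sorted within each operator level — because textual identity is brittle
and semantic equivalence is not decidable in general.

Compilation compares the two sides: unmapped reactant atoms become
deletions (with incident bonds), unmapped product atoms creations, and for
each mapped pair a charge/hydrogen/aromatic update is emitted only when
the product side pins a unique value not already pinned identically by the
reactant side. A product bracket atom with *no* charge primitive counts as
neutral when the reactant side constrains charge — this is what makes
`[C+,C++:1]>>[C:1]` a discharge instruction while
`[C+,C++:1]>>[C+,C++:1][H]` changes nothing. Ambiguous product hydrogen
expressions (`[CH2,CH1:1]`) compile without an H update and log a warning.

## Hydrogen handling

Three usage styles are supported. With explicit hydrogen atoms in both the
molecule and the rule (`[C:1][H:2]>>[C:1]O[H:2]`), hydrogens are ordinary
graph atoms and need no flags. With `h_atoms_transformation = TRUE`, H
primitives in atom expressions become edit instructions
(`[CH3:1]>>[CH2:1][OH]`); mode `IMPLICIT` edits the counts, `EXPLICIT`
adds or removes explicit H atoms (removal picks the lowest-index
candidates, a determinism choice the notation leaves open). With the flag
off, H primitives only constrain matching, and post-processing
(`process_result_structures = TRUE`) recomputes counts from the valence
model — the "automatic" style, whose results depend on the cleanup as much
as on the rule. A hydrogen count driven below zero raises an error.

## Stereo transformation

Stereo elements untouched by a site are always preserved. With
`apply_stereo_transformation = TRUE`, a ligand replaced by the reaction is
re-pointed to its replacement with parity preserved, and `@`/`@@` or
directional primitives on the product side create, flip or remove elements
(ligand order comes from the product pattern's written neighbour order,
mapped through the site). With the flag off, elements directly touched by
the edits are removed. Independently, `check_result_stereo = TRUE`
re-validates every surviving element on the final product: a tetrahedral
centre needs four live, distinct, pairwise non-equivalent ligands and a
4-coordinate focus; a cis/trans element needs its double bond and both
references. Equivalence of ligands is judged by whole-molecule
automorphism orbits *ignoring stereo*, so a centre bearing two
topologically equal branches is dissolved; this deliberately also removes
centres that would be distinguishable only by the stereo configuration of
their branches (meso-type cases) — a documented limitation.

## Reaction search

Three scenarios are covered: identity of two concrete reactions (multiset
identity of canonical SMILES), a generic rule against a concrete reaction
(each query component must embed in some reactant/product molecule, with
component groups constraining co-location), and a generic rule against
another generic rule. The last requires matching *expressions against
expressions*; inclusion ("every atom satisfying the query satisfies the
target") is decided by brute-force enumeration over a finite universe of
abstract atom descriptions — elements {B,C,N,O,P,S,F,Cl,Br,I} × charge
−2..+2 × total H 0..4 × aromaticity, with degree/ring/valence dimensions
expanded only when referenced. This favours correctness over speed and
makes the SPECIFIC↔GENERIC duality an enumerable property. Expressions
containing recursion are undecidable in this scheme; outside `EXACT` mode
they return `NA` with a warning and count as non-matches.

## What the fixtures emulate — and what they do not

The built-in fixture set (`fixture_set()`) reproduces in code the worked
molecules and rules the engine is documented against: the diamine matching
example, the propene/cyclohexene fragmentation pairs, 3-ethylpyridine
hydroxylation, dihydropyrrole aromatization, the five equivalent stereo
spellings, and the valid/invalid mapping examples. These are small (≤ 10
heavy atoms), drug-like fragments; passing the suite demonstrates correct
graph semantics on such inputs, not performance or robustness on
database-scale screening, macrocycles, organometallics, tautomer-sensitive
aromaticity, or polymer-sized molecules. Property tests deliberately stay
small so the oracles stay exact: brute-force match enumeration is run on
targets of at most 10 heavy atoms, and automorphism orbits are verified
against full permutation search on molecules of at most 8 atoms.

## Degenerate inputs and failure behaviour

Unkekulizable aromatic input, unbalanced brackets and unknown primitives
are errors with positions. Unparseable records in multi-record files are
skipped with a warning, never fatal. Overlapping sites in `ALL` or
`NON_IDENTICAL` in-place application may produce chemically impossible
molecules (e.g. over-valent carbons); that is the caller's responsibility
by design, but edits that would leave dangling references — one site
deleting an atom another site still maps — raise an application-conflict
error instead of corrupting the graph.

## Known limitations

* Ring perception is edge-shortest-cycle based, not a certified SSSR; ring
  counts on heavily fused cages may differ from other toolkits.
* The aromaticity model is a single fixed Hückel variant; perception-model
  differences with other software are expected on exotic rings.
* Allene stereo is parsed and carried but not created by transformation
  instructions; extended stereo beyond the three kinds is out of scope.
* Wedge/hash information in SDF input is ignored: no stereo is inferred
  from 0D connection tables.
* Isotopes do not refine equivalence classes, and isotope primitives in
  queries are rejected.
* `aromaticity_transformation` imposes product-side aromatic flags as
  written; it cannot verify that a larger ring system supports them.
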