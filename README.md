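# smirkr

Generic chemical reactions for R, written in the SMIRKS linear notation.

Medicinal and environmental chemists encode transformations — metabolic
hydroxylations, hydrolyses, standardization rules, retrosynthetic steps —
as *generic reactions*: rules that apply the same atom/bond changes to any
substrate. `smirkr` is a self-contained engine for such rules: it parses
SMILES molecules, SMARTS substructure queries (including recursive atom
environments `$(...)` and component-level grouping), and SMIRKS reactions
`reactants > agents > products`; validates the atom mapping; locates
reaction sites by subgraph matching; and applies the compiled
transformation with configurable hydrogen, aromaticity and stereochemistry
handling. It is aimed at R users who want rule-based structure
transformation and reaction searching without leaving R.

## The model in brief

A SMIRKS rule pairs reactant and product SMARTS atoms by map indices:

```
[C:1]=[C:2] >> [C:1][C:2]        # reduce a double bond, atoms conserved
C=C >> CC                        # same intent, unmapped: deletes + re-creates
[c:1][H] >> [c:1]O[H]            # aromatic hydroxylation
```

Unmapped reactant atoms are deleted (with their bonds), unmapped product
atoms created; mapped pairs contribute property and bond-order updates
derived by side-by-side comparison of the two expression graphs. Sites are
embeddings of the reactant pattern found by backtracking subgraph
isomorphism and filtered by a mode: `ALL`, `SINGLE`, `NON_IDENTICAL`
(distinct atom sets), `NON_OVERLAPPING` (a maximum pairwise-disjoint
family), or `NON_EQUIVALENT` (one representative per class of sites
related by graph automorphism). Stereochemistry is handled relatively
(`@`/`@@` parities and `/`,`\` directions against ligand order), with
preservation, ligand re-pointing, SMIRKS-driven creation/inversion/removal
and final re-validation.

## Worked example

Matching the query `CCN` against cyclohexane-1,2-diamine and applying
aromatic hydroxylation to 3-ethylpyridine:

```r
library(smirkr)

d  <- parse_smiles("NC1CCCCC1N")
ms <- find_matches(parse_smarts("CCN"), d)
length(ms)                                                    # 4
length(filter_mode(ms, "NON_OVERLAPPING"))                    # 2
length(filter_mode(ms, "NON_EQUIVALENT", equivalence_classes(d)))  # 2

rxn    <- parse_smirks("[c:1][H]>>[c:1]O[H]")
target <- hydrogens(parse_smiles("CCc1cccnc1"), "implicit_to_explicit")
res    <- apply_with_copies(rxn, target, transform_config())
for (p in res$products)
  cat(write_smiles(hydrogens(p, "explicit_to_implicit"), canonical = TRUE), "\n")
```

```
C(C)c1c(ccnc1)O
C(C)c1cc(cnc1)O
C(C)c1ccc(nc1)O
C(C)c1c(nccc1)O
```

The query fits the diamine at 4 places (two per amine, one per ring
direction); only 2 of them are pairwise disjoint, and the 4 fall into 2
classes of topologically equivalent sites. Hydroxylation of the 4 distinct
aromatic CH positions of 3-ethylpyridine yields the 4 pyridinol isomers,
one product copy per site.

A command-line wrapper is installed with the package
(`inst/scripts/smirkr`): `validate`, `match`, `apply`, `search` and
`fixtures` subcommands, with behaviour flags passed as
`--flag FlagSSMode=SSM_ALL` etc.

See the vignette `vignettes/smirks-transformations.Rmd` for the full
account of the model: valence and aromaticity conventions,
canonicalization, site-selection modes, mapping validation rules,
hydrogen-handling styles, stereo transformation semantics and known
limitations.

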