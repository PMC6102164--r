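Package: smirkr
Title: SMIRKS Reaction Transformations on Molecular Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained engine for generic chemical reactions written in
    the SMIRKS linear notation. Parses SMILES molecules, SMARTS substructure
    queries (including recursive atom expressions and component-level
    grouping) and SMIRKS reactions; validates atom mappings; locates reaction
    sites by subgraph matching in several modes (single, non-overlapping,
    non-identical, non-equivalent, all); applies the compiled transformation
    in place or as one product copy per site, with configurable handling of
    hydrogens, aromaticity and tetrahedral/cis-trans stereochemistry; and
    searches generic reactions against concrete and generic reactions.
    Includes SMILES/SDF (MDL V2000) input/output, canonical SMILES
    generation, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
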