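Package: cleftmatch
Title: Atomic-Level Geometric and Chemical Comparison of Protein Binding-Site Clefts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects small-molecule binding clefts in protein structures and
    measures atomic-level similarity between a query cleft and a dataset of
    known binding sites. Clefts are represented as graphs of typed heavy
    atoms; common substructures are found as cliques of an association graph
    in a two-stage matching procedure (a Calpha/residue-similarity stage that
    anchors a rigid superposition, then an all-atom stage on the superposed
    coordinates). Hits against a target dataset are ranked by the number of
    atoms in common and a Tanimoto score, with Z-scores computed under
    iterative outlier trimming and p-values from a standardized extreme-value
    (Gumbel) distribution. Includes a Surfnet-style gap-sphere cleft
    detector, ligand-defined cleft extraction, synthetic ground-truth
    generators for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
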