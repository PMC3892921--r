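---
title: "Measuring binding-site similarity by two-stage association-graph matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring binding-site similarity by two-stage association-graph matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleftmatch)
```

## The problem

Two proteins with unrelated folds can bind the same small molecule because
their binding clefts present similar constellations of atoms. Given a query
cleft — the heavy atoms lining a surface cavity — and a dataset of known
ligand-bound binding sites, `cleftmatch` asks: *what is the largest subset of
atoms in the two clefts that corresponds both chemically (same interaction
class) and geometrically (same pairwise distances)?* The size of that common
subset, and derived statistics, rank the dataset and suggest which ligands
the query might bind.

## Representation

A cleft is a complete edge-weighted graph: nodes are heavy atoms, each
carrying one of eight interaction classes (hydrophilic, hydrogen-bond
acceptor, donor, hydrophobic, aromatic, neutral, neutral-donor,
neutral-acceptor), and each edge carries the Euclidean distance between its
atoms. Standard-residue atoms are classed from a packaged lookup table
(`inst/extdata/sobolev_atom_types.tsv`), which transcribes the classic
interaction-class scheme for protein atoms: backbone N donor and O acceptor,
carbon neutral next to polar atoms and hydrophobic otherwise, aromatic ring
carbons aromatic, histidine ring nitrogens and serine/threonine/tyrosine
hydroxyl oxygens hydrophilic (both donor and acceptor). Het-group atoms are
classed by element plus bond context, with bonds inferred from covalent
radii (+0.45 Å tolerance); the two "neutral-donor/acceptor" classes are used
there for nitrogens without free hydrogen capacity and bridging
(ether/ester-like) oxygens, whose behaviour is ambiguous without protonation
information. This fallback is a documented approximation, not a claim of
equivalence with any particular reference implementation.

Finding the largest common subgraph of two clefts is cast as maximum-clique
detection in an *association graph*: each node is a pair of atoms, one per
cleft, with identical class; an edge joins nodes $k=\{i,t\}$ and
$l=\{j,s\}$ when

$$|d(i,j) - d(t,s)| \le D_{node},$$

so a clique is a set of atom pairs whose within-cleft distances mutually
agree — a chemically consistent, rigid common substructure. The slack
$D_{node}$ absorbs coordinate error and some side-chain flexibility.

## The two matching stages

Association graphs grow combinatorially, so matching runs in two stages:

1. **Residue stage.** An association graph over Cα atoms only, where two
   residues may pair when the minimum of their two directed substitution
   rank-orders under the Jones–Taylor–Thornton (JTT) model is at most
   $r$. The shipped `jtt_model.tsv` holds the published JTT
   exchangeabilities and equilibrium frequencies; rank$(a \to b)$ orders the
   19 substitution targets of $a$ by probability (exchangeability × target
   frequency), ties alphabetical, and identical residues always pair. The
   largest Cα clique (found exactly) defines a rigid superposition via the
   least-squares SVD method; cliques below 3 pairs cannot determine a rigid
   motion and yield a flagged "no superposition" result rather than a guess.
2. **Atom stage.** With the target moved into the query frame, an all-atom
   association graph pairs same-class atoms lying within $n$ Å of each
   other; edges again follow the distance-consistency rule. Cα atoms serve
   only as stage-1 anchors and are excluded here, so they never contribute
   to the similarity counts. The size $N_C$ of the largest clique is the
   number of atoms in common; the final transform is re-fitted on that
   stage-2 correspondence before any ligand comparison.

Fixed operating parameters (package defaults, overridable): $D_{node} = 4$ Å
at stage 2, $3.5$ Å at stage 1, $r = 5$, $n = 4$ Å.

### Clique detection

Exact mode is a deterministic branch-and-bound maximum-clique search with a
greedy-colouring bound, vertices in descending-degree order. The
approximate mode ("first clique") runs the pivoting maximal-clique
enumeration depth-first and returns the first maximal clique emitted,
exploiting the enumeration's tendency to produce large cliques early.
Within each recursion, candidates are ordered by their connectivity inside
the current candidate set (ties by node index): this keeps the first
descent inside the densest region and, on the 200-random-graph benchmark
used in the test suite, makes the first clique equal the maximum in 91% of
instances (a static degree ordering achieves only 75%). The approximate
result can never exceed the exact one. Exact mode falls back to the
approximate search, with a warning, beyond 3000 nodes or 5×10⁶ edges.

## Scores and statistics

For a query of $N_A$ atoms and target of $N_B$ (Cα excluded):

$$T = \frac{N_C}{N_A + N_B - N_C} \in [0, 1]$$

is the Tanimoto score of similarity. Over the population of all compared
entries, Z-scores use the population (not sample) standard deviation — the
per-hit z is a descriptive standardization against the whole searched
population, and at dataset scale the distinction is negligible; it is
pinned for reproducibility. Outliers with $z < -3$ or $z > 7$ are removed
and the moments recomputed, repeated until stable or at most five times;
final z-scores for *all* entries are taken against the final moments. The
p-value is the tail of a standardized Gumbel (extreme-value) distribution,

$$p = 1 - \exp\!\big(-e^{-z\pi/\sqrt6 + \gamma}\big), \qquad
\gamma = 0.5772157,$$

the $\pi/\sqrt6$ factor being the standardization of a unit-variance
Gumbel. A literal $\pi/6$ variant is kept behind a switch for comparison;
it does not reproduce the published score tables, while $\pi/\sqrt6$
matches every printed (z, p) pair within rounding (the test suite checks
all of them). Z-scores and p-values are computed independently for the
$N_C$ and $T$ populations, over the *searched* (cognate-filtered)
population, since the filter defines the dataset actually compared. A
degenerate population (zero spread) reports z = 0, p = 1, flagged.

Hits are ranked by $T$ descending, ties by $N_C$ descending then PDB code
(a sort-by-$N_C$ flag exists); since a larger site can have more atoms in
common yet a smaller $T$, both measures matter. An optional per-family
collapse keeps the best hit per Pfam accession.

## Cleft definition

Clefts come from three sources, all validated to contain at least four
atoms and the Cα of every represented residue:

* **Detection.** A gap-sphere cavity detector: for every atom pair whose
  van der Waals surfaces are separated by 2–8 Å, a sphere at the pair
  midpoint is shrunk until no atom penetrates it and kept if its radius
  stays in [1, 4] Å; overlapping spheres are clustered, clusters below
  50 Å³ (volume on a 0.5 Å grid) are dropped, and the three largest define
  clefts from their lining atoms (within sphere radius + 3 Å of a sphere
  centre). These constants are declared package parameters, pinned for
  tests, not claims about any historical server configuration. Restricting
  to one chain avoids inter-chain interface cavities.
* **Bound ligand.** Every residue with a heavy atom within 4.5 Å of a
  named het group, whole residues included. Residues are named in
  RESNUMCA form (`BTN300--`, `ASN94A-`); a bare residue code triggers
  prefix matching with an explicit candidate list on ambiguity.
* **User file.** A plain PDB fragment; ATOM records are the site, HETATM
  records an optional bound ligand.

Parsing keeps the first model of multi-model files, keeps one
alternate-location variant per atom (highest occupancy, ties
alphabetically), flags and excludes hydrogens and waters, and infers
missing element symbols from atom names. Insertion codes are retained
internally but are not representable in RESNUMCA, so identifier matching
ignores them; these conventions are this package's choices for cases the
identifier format does not cover.

## The synthetic ground-truth generator

Because real structure archives cannot ship with the package, validation
uses generated cleft pairs with a *provable* common core: cleft B carries a
jittered (default σ = 0.2 Å), rigidly moved copy of k planted atoms from
cleft A, plus distractors. Three design points make the ground truth a
theorem rather than a hope:

* **One core atom per synthetic residue.** Every planted atom contributes
  a Cα anchor. Grouping several atoms per residue was tried first and
  rejected: with only ⌈k/3⌉ Cα points in the 15 Å placement box, hundreds
  of non-identity point bijections are distance-consistent at the 3.5 Å
  stage-1 slack, and the resulting wrong superpositions (errors ~20 Å)
  destroy recovery. One-anchor-per-atom mirrors real clefts, where many
  residues line a site.
* **Distractors cannot reach the core.** Distractor atoms (three per
  residue, under synthetic nonstandard residue names that are
  substitution-compatible only with themselves and disjoint between the
  two clefts) are rejection-sampled at least 6 Å from every core atom, so
  they can neither join the planted stage-2 clique under the 4 Å proximity
  rule nor contribute stage-1 nodes.
* **Generation-time certificates.** The planted pairwise distance
  differences are verified against both stage bounds (a jitter too large
  aborts generation), and for small cores (≤ 8 residues) every
  distance-consistent Cα bijection is enumerated and required to induce a
  superposition keeping planted atoms within 3 Å of their partners —
  whichever maximum clique the matcher picks, the planted correspondence
  survives.

Synthetic datasets extend this: n entries in the package's index + PDB
dialect, a chosen number sharing the query's core, cognate-similarity
coefficients on the fixed grid 0, 0.05, …, 1, and a small synthetic ring
ligand per entry. Everything is bit-reproducible from the seed.

What passing these tests shows — and does not. They demonstrate that the
matcher recovers a known common substructure under noise, that the
statistics behave as specified, and that ranking retrieves planted signal
above background. Generated clefts have no covalent geometry, realistic
packing density, rotamers or secondary structure, so the tests say nothing
about detection sensitivity on real cavities or about biological
significance thresholds; for that, searches against curated datasets of
real binding sites are required (the loader accepts the published
7339-entry index layout via a column map).

## Numerical choices and degenerate inputs

* Superposition reflections are corrected by flipping the smallest
  singular direction; fewer than 3 pairs or collinear points raise a
  degenerate-superposition error.
* Cluster ranking and hit ranking have total, documented tie-breaks, so
  every search is bit-reproducible.
* p-values use `-expm1(-exp(·))`; in the far left tail (z ≲ −2.5) the
  value saturates to 1 at double precision.
* The ligand topological similarity table is a Tanimoto over
  element-labelled linear path fingerprints (paths of up to eight atoms,
  hashed to 1024 bits) on distance-inferred bonds — a comparative aid for
  judging whether top hits bind related ligands, documented as a stand-in
  rather than a reproduction of any published fingerprint.
* CLI precedence is defaults < config file < explicit flags, and every run
  writes its fully resolved parameter set to `run_log.txt`; exit codes are
  0 (success), 2 (input validation), 3 (runtime failure).

## Problem sizes used in validation

The shipped suite runs entirely on generated data: planted pairs up to
k = 20 with 15 + 15 distractors, a 50-entry dataset search with 5 planted
entries, 200 random 12-node graphs against a brute-force clique oracle,
and 20 random rigid motions — sizes chosen so the whole suite completes in
well under a minute while still exercising every code path at the method's
fixed parameters. Scaled-up runs only change population sizes, not any
algorithmic branch.

## Known limitations

* Atom classes assume standard protonation; no pH model.
* First NMR model only; no symmetry expansion or assembly handling.
* The gap-sphere detector's parameters are fixed package constants;
  cavities below 50 Å³ or beyond the third-largest are only reachable via
  the bound-ligand route.
* Exact clique search is exponential in the worst case; the safety valve
  to the approximate mode is logged but changes results slightly when it
  triggers.
* The similarity Z-score is descriptive, standardizing against the
  searched population; no multiple-testing correction across hits is
  attempted.
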