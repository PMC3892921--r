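# cleftmatch

Atomic-level comparison of protein small-molecule binding sites.

When sequence and fold give no functional clue, the *binding cleft* often
does: proteins that bind the same ligand tend to present similar
constellations of atoms, even across unrelated folds. `cleftmatch` detects
or defines a query cleft in a PDB structure and searches it against a
dataset of known ligand-bound binding sites, reporting which atoms
correspond, how the sites superpose, and how surprising each match is. It
is aimed at structural biologists annotating structures of unknown
function, and at anyone studying cross-reactivity or ligand repurposing
from structure.

## The method

A cleft is a set of typed heavy atoms (eight interaction classes:
hydrophilic, acceptor, donor, hydrophobic, aromatic, neutral,
neutral-donor, neutral-acceptor). Comparing clefts *m* and *n* is cast as
maximum-clique detection in an association graph whose nodes are same-class
atom pairs {*i*, *t*} and whose edges require geometric consistency

|d(i,j) − d(t,s)| ≤ D_node,

so a clique is a subset of atoms in each cleft whose pairwise distances
mutually agree — a common rigid substructure. Matching runs in two stages:
a Cα-only graph (residues paired when their JTT substitution rank-order ≤
r = 5; D_node = 3.5 Å) whose largest clique anchors a least-squares rigid
superposition, then an all-atom graph over same-class atoms within n = 4 Å
after superposition (D_node = 4 Å). The stage-2 clique size N_C and the
Tanimoto score

T = N_C / (N_A + N_B − N_C)

rank the hits; Z-scores over the searched population (iteratively trimmed
at z < −3 / z > 7, at most five passes) get extreme-value p-values from the
standardized Gumbel tail p = 1 − exp(−e^(−zπ/√6 + 0.5772157)). Cliques are
found by an exact branch-and-bound search or a deterministic
first-maximal-clique heuristic that is near-optimal at a fraction of the
cost.

## Worked example

Everything below runs offline on generated data with known ground truth: a
50-entry synthetic dataset in which 5 entries share a planted 20-atom core
with the query (0.2 Å jitter, 15 distractor atoms per cleft).

```r
library(cleftmatch)

spec <- planted_pair_spec(k_common = 20, n_noise_a = 15, n_noise_b = 15,
                          jitter_sigma = 0.2, seed = 11)
ds      <- make_synthetic_dataset(50, 5, spec, seed = 3)
entries <- load_dataset(ds$root)
hits    <- run_search(ds$query, entries, top_k = 5)
hits
#> search over 50 entries; top 5 hits:
#>   rank pdb_code ligand_code n_common z_nc   p_nc tanimoto  z_t    p_t
#> 1    1     s003         L03       21 3.01 0.0370    0.429 3.12 0.0319
#> 2    2     s001         L01       20 2.80 0.0477    0.400 2.85 0.0451
#> 3    3     s002         L02       20 2.80 0.0477    0.400 2.85 0.0451
#> 4    4     s004         L04       20 2.80 0.0477    0.400 2.85 0.0451
#> 5    5     s005         L05       20 2.80 0.0477    0.400 2.85 0.0451
```

The five planted entries (`s001`–`s005`) occupy the top five ranks:
`n_common` is the number of atoms in correspondence (≥ the planted 20; s003
picked up one coincidental extra pair), `tanimoto` the shared fraction of
the combined sites, and each score carries its trimmed Z-score and
extreme-value p-value over the 50-entry population. A pairwise comparison
exposes the superposition and the correspondence itself:

```r
compare_clefts(entries[[1]]$cleft, entries[[2]]$cleft)
#> <similarity: N_C=20 N_A=35 N_B=35 T=0.400 ligand RMSD=0.10 A>
```

— the two entries share the same planted core, so their bound ligands
superpose to 0.1 Å when the target is moved by the fitted transform.
`report(hits, entries, "out/")` writes the hit table (TSV), one
superposed-ligand PDB and one correspondence table per hit, and the
pairwise ligand topological-similarity matrix.

The same pipeline is scriptable from the shell (see
`inst/cli/cleftmatch`): `detect` (three largest cavities of a structure),
`compare`, `search` (with `--ligand BTN300--`-style cleft definition,
`--cognate-min`, `--per-pfam`) and `fixtures`.

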