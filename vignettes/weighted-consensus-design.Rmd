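---
title: "Branch-weighted consensus design and thermostability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch-weighted consensus design and thermostability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloconsensus)
library(ape)
```

## The problem

Consensus design proposes stabilizing point mutations by replacing a residue
of a target protein with the residue most frequent at that position across a
family of homologs: positions conserved across evolution tend to be
stabilizing. Its classic failure mode is database bias. Public sequence
collections oversample some subfamilies (well-studied genera, resequenced
strains), so a plain majority vote at each alignment column reflects
sampling effort, not evolutionary preference. A residue fixed in one
oversampled clade can outvote the residue that the rest of the family — and
the family's ancestor — actually carries.

`phyloconsensus` removes that bias by weighting every sequence by its
phylogenetic novelty before the vote. The package covers the full design
loop: alignment intake and pre-filtering, distance-based tree building,
branch-length weights, weighted consensus, structural screening of the
candidate substitutions, and the downstream thermostability assays used to
judge the resulting variants (half-life, T50, Tm, fold improvements).

## The method, step by step

### Distances and tree

Pairwise distance between two aligned homologs is the number of columns
where both carry a residue and the residues differ, divided by the *smaller
ungapped length* of the two sequences (`pairwise_distance()`). This reduces
to the usual p-distance for gap-free pairs and stays in [0, 1]. The tree is
built with the textbook Saitou–Nei neighbor-joining agglomeration
(`neighbor_joining()`), re-implemented here rather than delegated so that
tie-breaking is deterministic (lowest index pair in input order) and runs
are reproducible without external software; on additive matrices it
provably recovers the generating tree, which the test suite checks against
brute-force topology enumeration. Negative limb lengths — a known NJ
artifact on noisy matrices — are clamped to zero with the clamped total
recorded on the tree. Rooting uses a distant outgroup: the root is placed
at the midpoint of the outgroup's terminal edge (`root_with_outgroup()`;
the split fraction is configurable), which changes no leaf-to-leaf path
length.

### Sequence weights

The weight of leaf $a$ is

$$W_a \;=\; \sum_{e \,\in\, \mathrm{path}(\mathrm{root},\,a)}
\frac{\ell_e}{n_e},$$

where $\ell_e$ is the branch length of edge $e$ and $n_e$ the number of
(non-outgroup) leaves below it; weights are then normalized to sum to one.
This is the Gerstein–Sonnhammer–Chothia scheme familiar from ClustalW
alignment weights: an edge shared by a whole subfamily is split evenly
among its members, so $k$ near-identical database entries share the weight
a single entry would have received, while an isolated deep-branching
sequence keeps its full path. Two consequences are worth stating because
the tests rely on them: weights are invariant to a global rescaling of
branch lengths, and attaching $k$ zero-length copies of a leaf to a star
tree leaves that subfamily's total share exactly unchanged. On non-star
topologies exact neutrality cannot hold — duplications change the
descendant counts of edges shared with other leaves — but the deviation is
small and bounded, which is why that property is asserted at tolerance
rather than exactly. The outgroup exists only to place the root: it is
excluded from the weights and from the consensus.

The weighting formula is exposed as its own function (`branch_weights()`)
and treated as a swappable strategy; it is our declared interpretation of
"the weighted sum of the average distance of root-node branches", chosen
because it matches both that description and the de-biasing purpose.

### Weighted consensus and candidate sites

At every column where the query carries a residue, `column_frequencies()`
computes weight-normalized frequencies of the 20 amino acids plus a gap
mass. Unknown residues (`X`) are pooled with the gap mass: they never count
toward a match and can never be proposed as a consensus residue, so the 20
frequencies plus gap mass always sum to one. `candidate_sites()` emits a
substitution when the top residue differs from the query's and its
frequency exceeds the cutoff (default 40%, the screening-budget dial). Two
conservative choices: the cutoff is tested against *total* weight
including gaps, so a residue must clear it absolutely (a `"nongap"`
denominator is available); and an exact tie for the top residue emits
nothing, because an ambiguous column has no consensus. Positions are
numbered 1-based on the ungapped query, giving the conventional `D17V`
labels.

### Structural screening

Stabilizing candidates should not touch catalysis or existing
interactions. Given a query structure (PDB) and a declared active-site
residue or ligand set, `apply_structural_filters()` rejects a site when its
minimum heavy-atom distance to the active site is 6 Å or less
(`rejected_distance`), else when its side chain already makes a hydrogen
bond or salt bridge (`rejected_bonded`), else marks it `passed` — nothing
is deleted, so the output is a full audit trail. Bond detection is
geometric and distance-only: side-chain N/O to any N/O within 3.5 Å counts
as a hydrogen bond (backbone partners allowed — the criterion concerns the
candidate's own side chain), and a side-chain charged nitrogen (Lys NZ,
Arg NH1/NH2/NE, His ND1/NE2) within 4.0 Å of a side-chain carboxylate
oxygen (Asp OD1/OD2, Glu OE1/OE2) counts as a salt bridge. Angle terms and
hydrogens are deliberately out of scope — homology models rarely have
trustworthy hydrogens — so the detector should be read as a conservative
contact screen, not an energy model. Active-site distances depend strongly
on the model used; treat them as screening quantities, not reproducible
observables.

## Thermostability readouts

Three standard assays quantify whether a variant worked:

* **Half-life** (`fit_half_life()`): first-order inactivation. Ordinary
  least squares of $\ln(\mathrm{activity}/100)$ on incubation time;
  $T_{1/2} = -\ln 2 / k$. "The linear part of the curve" is made concrete
  as: points with activity at least 5% of the initial value (low
  activities dominate log-space noise); an explicit time window overrides
  this.
* **T50** (`fit_t50()`): residual activity after a fixed incubation at a
  ladder of temperatures, fitted with the Boltzmann sigmoid
  $y = A_2 + (A_1 - A_2)/(1 + e^{(T - T_{50})/dT})$ by Levenberg–Marquardt
  least squares with deterministic initialization ($A_1 = \max y$,
  $A_2 = \min y$, $T_{50}$ at the mid-range point, $dT = 2$ °C).
  Activities are normalized so the lowest-temperature point reads 100%.
* **Tm** (`fit_tm()`): nanoDSF melting temperature — the peak of the first
  derivative of the 350/330 nm fluorescence ratio. The ratio is fitted
  with a degree-9 polynomial and the derivative maximum located on a
  0.01 °C grid. One numerical choice matters here: a single global
  polynomial cannot follow a sharp two-state transition across a 75 °C
  ramp (Runge oscillation pushes the derivative maximum to the ramp edge),
  so the transition is first localized by the steepest finite-difference
  slope of the median-smoothed signal and the polynomial is fitted within
  ±15 °C of it. Degree, grid, and window are configurable. A missing
  interior derivative peak (flat or truncated curve) raises a boundary
  warning rather than returning a fabricated Tm.

`fold_improvement()` and `summarize_variants()` turn fitted half-lives into
the conventional comparison table: fold = variant / reference, reported to
1 decimal at ≥ 10 and 2 decimals below (`round_fold()`), and the design
success rate is the integer percentage of variants with fold > 1.

## The simulator, and what passing tests mean

`simulate_family()` evolves an ancestor down a known tree (per edge of
length $\ell$, each site substitutes with probability $1 - e^{-r\ell}$,
uniformly to one of the other 19 residues), so distance, tree, weight, and
consensus code can be tested against exact ground truth.
`bias_family()` reproduces the failure mode the package targets: it
attaches near-identical copies (branch 1e-4) inside a chosen clade and
plants clade-specific substitutions whose residue then wins a plain
majority vote while branch weighting still recovers the ancestral residue.
`simulate_decay()`, `simulate_t50()` and `simulate_melt()` generate assay
curves with known parameters and seeded noise.

The simulator is deliberately idealized: indel-free, uniform replacement
(no JTT/WAG-style exchangeabilities), no rate heterogeneity across sites,
and noise models that are exactly the ones the fitters assume. Passing
tests therefore demonstrate correctness of the algorithms under their own
assumptions — they do not show that a 40% cutoff or a 6 Å radius is optimal
for any particular enzyme, nor that real NCBI families are as well-behaved
as simulated ones. Gap handling, which the simulator omits, is covered by
hand-built fixtures instead.

Default study conditions used by the tests and the acceptance script: an
8-leaf balanced tree (branches 0.05), 120-site ancestors, rate 1, one clade
of two leaves oversampled with 5 extra copies, two planted sites per
family, 20 seeded families; 100 seeded replicates for each assay-recovery
check. These sizes keep every property estimable while the whole suite
runs in well under a minute.

## A worked example

```{r example}
tr <- read.tree(text = paste0(
  "(((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05):0.05,",
  "((E:0.05,F:0.05):0.05,(G:0.05,H:0.05):0.05):0.05);"))
set.seed(1)
anc <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                    120, replace = TRUE), collapse = "")
sim <- simulate_family(tr, anc, rate = 1, seed = 1)
biased <- bias_family(sim, c("G", "H"), extra_copies = 5, seed = 1001,
                      n_planted = 2)

rooted <- root_with_outgroup(
  neighbor_joining(distance_matrix(biased$family)), "A")
w <- branch_weights(rooted)
prof <- column_frequencies(biased$family, w)
candidate_sites(prof, cutoff = 40)
biased$planted
```

The planted clade-specific residues dominate a uniform vote (7 of 13
sequences) but not the weighted one, so they do not appear among the
weighted candidates.

```{r assays}
cv <- simulate_decay(-log(2) / 11.6, seq(0, 35, 5), variant = "M0")
fit_half_life(cv)$t_half
fit_t50(simulate_t50(55.5))$t50_15
fit_tm(simulate_melt(59.6))$tm
```

## Known limitations

* The p-distance is uncorrected; for very divergent families a
  model-corrected distance would be preferable, but the method's weights
  only need relative branch lengths, which the p-distance serves.
* NJ tie-breaking makes runs deterministic, not "correct": on highly
  symmetric matrices several topologies are equally valid.
* The weighted consensus can still be overturned when oversampling is
  extreme enough to dominate the estimated tree itself (the clade's stem
  edge absorbs weight); the acceptance metrics quantify how often this
  happens under the default conditions.
* Bond detection has no angular term and no hydrogens; it is a screen.
* Structural distances are only as good as the supplied model and
  active-site declaration.
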