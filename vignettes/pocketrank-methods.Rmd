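---
title: "Ranking candidate ligand-binding pockets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking candidate ligand-binding pockets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketrank)
```

Most proteins expose several surface clefts and internal cavities, but a
ligand binds in only one or two of them. Pocket *detection* is therefore only
half of binding-site prediction; the harder half is *ranking* the candidates
so that the biologically relevant pocket comes first. pocketrank implements a
complete, self-contained version of this workflow: geometric pocket
detection, four per-pocket ranking properties, consensus ranking by
Cross-Entropy minimisation of the Spearman footrule distance, and the
standard hit-criterion/TOP-n/MCC evaluation protocol.

## Pocket detection: the PSP grid scan

`find_pockets()` rasterises the polymer heavy atoms onto a cubic grid
(default spacing 1.0 Å, 8 Å solvent margin) and marks every voxel within
2.0 Å of a heavy atom as *protein*. For each remaining *solvent* voxel it
counts protein–solvent–protein (PSP) events: along each of 7 scan axes (x,
y, z and the four cube diagonals) the voxel scores one event when protein
voxels flank it on both sides. Buried solvent accumulates high counts;
open solvent scores near zero. Voxels with at least 5 of 7 events are
clustered into 26-connected components, and components of at least 30
voxels become pockets.

These defaults are configuration-exposed choices of this implementation,
not quantities estimated from data: 1 Å spacing resolves cavities a few
Ångström across without inflating the grid; the 5/7 threshold accepts
pockets that open to solvent in one or two directions while rejecting
shallow surface texture; 30 voxels (≈30 Å³) is roughly the smallest void
that could hold a fragment-sized ligand.

Two implementation details matter for reproducibility:

* **Lattice-snapped grids.** The grid origin is snapped to the global
  spacing lattice, so voxel centres sit on integer multiples of the
  spacing. A 90° rotation of the input about a lattice axis then maps
  voxel centres onto voxel centres exactly: pocket counts, sizes and
  volumes are invariant and centres rotate exactly, which the test suite
  asserts.
* **Deterministic pocket ids.** Components are numbered 0, 1, 2, … by
  decreasing voxel count, ties broken by the lexicographically smallest
  member voxel. Every downstream ranking is therefore reproducible
  byte-for-byte.

## The four ranking properties

For each pocket, `pocket_properties()` computes:

* **Volume** (Å³) — the convex-hull volume of the pocket's grid points.
  Bigger pockets are ranked better (the classical "largest pocket"
  heuristic).
* **Distance** (Å) — the Euclidean distance
  \(d = \sqrt{(x_b-x_p)^2 + (y_b-y_p)^2 + (z_b-z_p)^2}\)
  between the pocket centre \((x_b,y_b,z_b)\) and the protein centroid
  \((x_p,y_p,z_p)\); smaller is better, as deep pockets sit close to the
  centroid. The centroid is the unweighted mean of polymer heavy atoms —
  mass weighting was rejected as it changes nothing qualitatively and
  adds an element-table dependency.
* **Conservation** — the arithmetic mean of the normalised per-residue
  conservation scores (ConSurf convention: mean 0, SD 1 over the protein,
  negative = conserved) over the pocket's lining residues; more negative
  is better. The *mean* rather than the *sum* is used deliberately: a sum
  would grow with pocket size and confound conservation with volume,
  which the workflow treats as a separate, complementary property. The
  choice is switchable in principle but the mean is the package default
  throughout.
* **Hydrophobicity** — the count \(N_H\) of lining residues whose type is
  one of ALA, VAL, LEU, ILE, PRO, PHE, TRP, MET; larger is better. This
  is intentionally the crudest of the four properties (a plain count, no
  hydropathy scale), kept simple to match its role as a weak baseline.

Lining residues are those with any heavy atom within 5.0 Å (inclusive) of
any pocket grid point. All tie-breaks are by ascending pocket id.

Pockets whose lining residues all lack conservation data are excluded
from the conservation ranking only, with a warning; the truncated-rank
convention below handles their absence during aggregation.

## Consensus ranking

Given ranked lists \(L_1,\dots,L_m\) over the same pocket universe, the
truncated rank of item \(t\) in \(L_i\) is its position if \(t\) is within
the top \(k\), and \(k+1\) otherwise. The Spearman footrule distance

\[ d(L_i, L_j) = \sum_{t \in L_i \cup L_j} \lvert r_{L_i}(t) - r_{L_j}(t) \rvert \]

sums absolute rank differences over the union, and the consensus list is

\[ \delta^* = \arg\min_\delta \Phi(\delta), \qquad
   \Phi(\delta) = \sum_{i=1}^m W_i\, d(\delta, L_i), \]

with importance weights \(W_i\) defaulting to 1 (all properties treated
equally). By default \(k\) equals the size of the shared pocket universe,
i.e. full lists are aggregated; shorter lists (e.g. a conservation
ranking that had to drop pockets) are handled by the \(k+1\) rule rather
than by re-indexing. Scores attached to a ranked list are carried along
for reporting but play no role in the distance, which is rank-based by
construction.

`ce_aggregate()` minimises \(\Phi\) with the Cross-Entropy method: a
\(k \times n\) position/item probability matrix (initially uniform) is
sampled \(N\) times per stage — positions filled sequentially, without
replacement — the elite fraction \(\rho\) with the lowest \(\Phi\) is
kept, and the matrix is re-estimated from the elite with multiplicative
smoothing 0.7 (full replacement converges prematurely on small
problems). Defaults follow the usual CE guidance for permutation
problems: \(N = \max(10k^2, 100)\) and \(\rho = 0.01\) for \(N \ge 100\)
(0.1 for smaller \(N\)); the run stops after 10 stages without
improvement (`stall_limit`) or 100 stages. The best list ever sampled is
returned and its \(\Phi\) is recomputed exactly with `objective_phi()`,
so the reported objective is never a sampling artefact. With a fixed
seed the whole optimisation is bit-reproducible.

`brute_force_aggregate()` enumerates all ordered top-\(k\) lists (up to a
10⁶ cap) and returns *every* minimiser — \(\Phi\) regularly has ties
because it is integer-valued. It is the exact oracle the test suite
holds the CE optimiser to: on 100 seeded random problems over up to 6
items the two agree on the minimum in well over 95% of cases, and CE can
never report an objective below the enumerated minimum.

## Evaluation protocol

A prediction *hits* when the pocket's geometric centre lies within 4.0 Å
(inclusive — the boundary convention is documented rather than implied)
of any heavy atom of any ligand. Ligands are non-water hetero groups
with ≥ 6 heavy atoms, which automatically discards buffer ions. The
TOP-n success rate is the fraction of *all submitted* proteins whose
best hit comes at rank ≤ n; proteins that never hit count as failures in
the denominator (the only reading under which rates below 100% are
possible).

Residue-level agreement uses the Matthews correlation coefficient over
TP/TN/FP/FN, where *actual* binding residues have a heavy atom within
4.0 Å of a ligand heavy atom (configuration-exposed; the choice mirrors
the hit cutoff) and *predicted* residues are the rank-1 pocket's lining.
When a denominator factor is zero the MCC is defined as 0, the standard
degenerate-table convention. Paired method comparisons use the one-sided
Wilcoxon signed-rank test on per-protein MCC vectors; zero differences
are dropped, and an all-zero difference vector raises an error rather
than fabricating a p-value.

Bound/unbound evaluation expects ligand coordinates already expressed in
the evaluated structure's frame; structural superposition to transfer
ligands between crystal forms is out of scope.

## The synthetic-fixture generator

`make_structure()` builds toy proteins so the whole pipeline is testable
without downloads: carbon pseudo-atoms (one per "residue") on a jittered
cubic lattice filling a ball, spherical cavities carved by atom deletion,
a planar 10-carbon ring written as HETATM records in the designated
cavity, and per-cavity flags for hydrophobic lining (80% hydrophobic
draws) and conservation. `make_conservation()` gives every residue a
standard-normal score, shifts conserved cavity linings by −2, and
re-standardises to mean 0 / SD 1, matching the ConSurf normalisation.

Generator geometry was chosen once, from first principles:

* **A solid ball, not a hollow shell.** A shell of atoms would enclose
  one giant interior void that swamps PSP detection and makes the
  centroid-distance property meaningless; a filled ball gives the
  detector the same figure/ground structure as a globular protein.
* **2.0 Å lattice, 0.25 Å jitter.** At 2.0 Å spacing the 2.0 Å occupancy
  radius seals the interstitial space (worst-case body-centre gap
  \( \sqrt{3} \approx 1.73\) Å), so only carved cavities read as buried
  solvent; the jitter breaks lattice artefacts without opening pinholes.
  This packs heavy atoms about as densely as a real protein interior, so
  a ~900-pseudo-residue fixture is physically the size of a much smaller
  real chain.
* **Demonstration conditions.** The demo/acceptance fixtures carry two
  cavities: the true site (radius 4.5 Å, conserved, ligand-bearing,
  4.75 Å from the centre) and a decoy (radius 4.0 Å, unconserved,
  5.9 Å out). Each informative property thus has a real signal to find —
  the true pocket is larger, deeper and more conserved — while
  hydrophobicity remains uninformative by construction. Cavity radii sit
  just above the detection floor: after the 2 Å occupancy erosion a
  radius-4 cavity leaves a ~70-voxel void, comfortably above the
  30-voxel minimum, while radius ≤ 3.5 Å cavities vanish.

What the fixtures deliberately do **not** emulate: side-chain chemistry
and rotamers, irregular pocket shapes, partial burial, crystallographic
water, multi-chain interfaces, and realistic conservation correlation
along the sequence. Passing the planted-pocket tests therefore shows the
machinery is correct and well-calibrated for unambiguous geometry; it
does not certify real-data accuracy, for which external benchmark sets
with curated conservation profiles are required.

With only a handful of pockets per toy protein, rate estimates are
coarse (steps of 1/25 in the standard batches) and the ascending-id
tie-break — ids correlate with pocket size — can flatter weak properties
such as the hydrophobic count; both effects are visible in the demo
table and are artefacts of the small synthetic universe, not of the
method.

## Numerical choices

* **Convex-hull volumes** (pocket size) are computed by an incremental
  3-D hull with a deterministic joggle of 10⁻⁵ × the bounding-box
  extent. Pocket grid points are pathologically degenerate for hull
  codes (every 4 coplanar lattice points are a tie), and the joggle puts
  them in general position so exact-sign orientation tests are reliable;
  the volume perturbation is O(area × joggle), about 10⁻⁴ relative,
  orders of magnitude below anything the volumes are used for. Inputs
  that are coplanar *before* joggling report volume 0 with a warning.
  The implementation is cross-checked in the test suite against an
  independent Qhull computation and closed-form solids.
* **Problem sizes.** The standard batches are sized for quick,
  repeatable runs on one CPU: 25 two-cavity fixtures for the ranking
  study (a ~1700-atom fixture takes ~0.3 s to detect), 100 random
  problems for the optimiser-vs-oracle sweep, 20 randomized fixtures
  for the geometric-recovery property. Each batch is seeded and
  reproducible.
* **Determinism.** Every stochastic component (fixture generation,
  conservation profiles, CE sampling) takes an explicit seed; the
  pipeline derives per-protein CE seeds from the run seed, and run
  reports serialize their full configuration. Two runs with the same
  configuration and seed produce byte-identical outputs.

## Known limitations

The PSP detector inherits LIGSITE-family weaknesses: very shallow,
bowl-shaped sites score few PSP events, and grid anisotropy makes
detection of near-threshold cavities orientation-sensitive (exact only
for 90° lattice rotations). The hydrophobic property is a bare count and
is expected to rank poorly on realistic inputs. Conservation profiles
are consumed, never computed — garbage profiles give garbage rankings.
The evaluation's residue-level MCC depends on the lining cutoff; with
the generous 5 Å lining default the predicted set is typically larger
than the 4 Å actual binding set, which caps attainable MCC on the toy
fixtures well below 1.
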