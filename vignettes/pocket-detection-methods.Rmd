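---
title: "Probe-sphere pocket detection and isolation-forest ranking: methods"
author: "probepocket"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-sphere pocket detection and isolation-forest ranking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A protein's solvent-excluded surface (SES) is the boundary traced by a
spherical solvent probe rolling over the van der Waals spheres of the
atoms. Its concave, re-entrant patches are generated by probe positions
simultaneously tangent to three atoms. `probepocket` detects binding
pockets from exactly these primitives: for every probe radius on a ladder
from 1.4 Å (water) to 3.0 Å in 0.1 Å steps (17 levels), all clash-free
probe spheres tangent to an atom triplet are enumerated by solving the
three-sphere tangency system analytically. A pocket is then a cluster of
such probes, grown by a tailored hierarchical clustering over the ladder.

### Clustering events

Only probes of equal radius, or radii differing by one increment
δ = 0.1 Å, may cluster, through four event types:

* **bottleneck** — two probes on opposite sides of the same trimming
  plane (the plane through the three tangent atom centers), whose center
  projections onto that plane coincide (tolerance 0.1 Å) and fall inside
  the triangle of atom centers. This seals a narrowing of the surface.
* **radial shift** — probes of radius r and r + δ tangent to the same
  triplet on the same side. Maximal runs of such links over consecutive
  levels form *chains*; the number of aligned probes is the chain's
  *depth index*. When the local surface becomes insensitive to probe
  size, probes align this way: a chain of depth ≥ 4 (the
  significant-alignment threshold) is a *pseudo-mouth*.
* **lateral aggregation** — equal-radius probes tangent to the same two
  of three atoms, each center lying on the other probe's side of the
  other's trimming plane, with surface gap d − (rᵢ + rⱼ) ≤ γ.
* **pyramidal aggregation** — probes one increment apart on different
  triplets with surface gap ≤ β.

γ and β are the only tuned parameters; the deployment optimum is γ = 0
(touching-or-overlapping probes) and β = 0.9 Å. Reading γ as a surface
gap rather than an absolute distance is deliberate: with an absolute
reading, γ = 0 would disable lateral aggregation outright.

Per level the engine applies same-radius bottlenecks, then lateral
aggregation; between consecutive levels, bottlenecks, then pyramidal
merges and radial shifts — each pass processing candidate pairs in
ascending distance (ties by probe id, which the distance-sorting
prescription leaves open). Merges are union-find over cluster nodes, so
the merge history is a binary tree whose event lists (aggregation,
persistence, bottleneck) are accumulated bottom-up.

### Pockets, subpockets, entrances

A cluster qualifies as a (conventional) pocket when it holds at least 100
probes and contains at least one pseudo-mouth. Because both size and
chain count grow monotonically up the tree, qualifying nodes are
upward-closed: pockets are the qualifying roots, and *subpockets* are the
minimal qualifying descendants — the irreducible representation of a
composite site. A pocket owning subpockets is a *master*.

Entrances are found by single-linkage clustering of chain-terminal probes
with radius > 2.4 Å under the power-distance orthogonality rule
(d² ≤ rᵢ² + rⱼ²). Each entrance carries the arithmetic mean of member
centers (the "geometric center" is read as the arithmetic mean), an
effective radius (mean distance to that center plus mean member radius),
an average depth index, and the terminal probes' mean trimming-plane
normal (the reference plane for an entrance normal is not pinned down
elsewhere, so the terminal probe's own plane is used). A pocket with no
qualifying terminal probe is *buried*; for subpockets the separate 2.5 Å
constant applies to the terminal sphere radius. The two constants
(2.4 Å grouping, 2.5 Å buried test) are kept as distinct configurable
values rather than unified.

## Descriptors

Each pocket is described by 17 geometric/clustering features
(entrance count and radii, entrance depth score normalized by the
alignment threshold so 1 is the minimum pseudo-mouth, bottleneck count
and mean radius, large-aggregation statistics, volume, size, aggregation
/ persistence / clustering scores normalized by cluster size, volume
ratio, Wadell sphericity ψ = π^(1/3)(6V)^(2/3)/A, ramification, and
protrusion) and 22 chemical features (the 20 residue fractions over
distinct pocket residues, plus hydrophobic and hydrophilic scores under a
bundled binary hydropathy table in which glycine is neutral — counted in
the denominator but in neither class). A residue belongs to a pocket if
any of its atoms is tangent to a member probe.

Reading choices where the verbal definitions leave room:

* *Ramification* is the standard deviation of the persistence list
  (sample SD; a singleton list gives 0, as do all persistence-derived
  features of a pocket with no significant chains).
* *Protrusion* is read literally as (un-normalized entrance depth) −
  mean(persistence) − ramification, i.e.
  `entrance_depth_score × 4 − mean(persistence) − ramification`.
* *Large aggregations* are lateral/pyramidal merges whose pre-merge
  cluster sizes are both above 10 and within a 1:5 ratio.

### Volume and area of the probe cloud

Pocket volume and area are computed on the union of member spheres. The
exact path integrates a signed-distance grid (default spacing 0.3 Å)
with a linear sub-voxel occupancy, and samples each sphere with a
deterministic Fibonacci lattice, counting points not buried in any other
sphere — the same exposure-counting scheme used for solvent-accessible
areas; it converges to analytic values (single sphere, two-sphere lens)
as the spacing shrinks. For clouds beyond 400 spheres a gridded estimator
takes over: spheres are rasterized by radius group and dilated by an FFT
ball kernel (volume), and the area comes from boundary voxel faces with
the 2/3 isotropic-staircase correction. The switch keeps feature
extraction on thousands-of-probe pockets tractable; there volume feeds
the ranking, not any analytic comparison. The exported pocket "mold" is
the boundary-voxel quad mesh — a visualization artifact; volume and area
are never read from it.

## Ranking: one-class learning with Isolation Forests

Declaring negatives is the perennial problem of binding-site scoring:
a region never observed binding may simply not have met its ligand.
The ranking therefore treats scoring as one-class anomaly detection.
An Isolation Forest grows binary trees on random subsamples (size 256, no
bootstrap) by uniformly random feature/split choices up to height
⌈log₂ n⌉; the anomaly score of x is s(x) = 2^(−E(h(x))/c(n)), with h the
path length in edges (extended below non-singleton leaves by c(leaf
size)) and c(n) the mean unsuccessful-search path of a binary search tree.
Scores near 1 flag anomalies — implausible pockets; low scores flag
"normal", binding-site-like pockets, so ranking is ascending in s.

Training uses hitting pockets only (LC ≥ 50%, PC ≥ 20%; see below), each
replicated max(1, round(10 × PC)) times — "proportional to PC" leaves
the constant open; 10 maps PC = 100% to ten copies and keeps single
copies below PC = 15%. Rows split into a **large** population (master
pockets with more than one subpocket) and a **small** population
(everything else, including subpockets); one geometric and one chemical
forest per population — four forests total. The large-population pair
scores all top-level pockets (final score = mean of the two forests);
the small-population pair only sub-ranks subpockets within their master.
Ties break by larger volume, then pocket id (the ordering is otherwise
unspecified). A population with no rows falls back to the pooled rows,
so tiny training sets remain usable. At deployment 10 000 trees are the
reference configuration; tests and examples use 100–200 trees, which is
statistically equivalent for the contracts checked and far cheaper.

In the single-pocket protocol each master is replaced by its at most
three top subpockets, scored by a penalized master score. The penalty's
published functional form is not recoverable from the source text (only
its properties are stated: identity at subrank R = 1, worsening with R),
so the package defines s_R = 1 − (1 − s)/R: the pocket's "normality
margin" 1 − s is divided by the subrank, which is the identity at R = 1,
non-improving in R, and stays inside (0, 1).

## Evaluation metrics

With "contact" meaning a center-to-center distance below 5 Å
(atom centers; radii are never inflated), **Ligand Coverage** is the
fraction of ligand heavy atoms contacting the pocket among those
contacting the protein, and **Pocket Coverage** is the symmetric
fraction of pocket atoms contacting the ligand. Scores are percentages
rounded *up* at 0.1 resolution ("rounded up" is taken literally as a
ceiling). A pocket is a hit at LC ≥ 50% and PC ≥ 20% (inclusive). For
apo structures both metrics run on residues: pocket residues against the
mapped binding-site residues, a residue being in contact if any
heavy-atom pair is within the cutoff. A ligand contacting no protein
atom has undefined LC; such sites are excluded from normalization with a
warning. Ranked lists are summarized by Top-N rates, where a site's rank
is the number of non-matching pockets above its first match and
normalization is per binding site, not per structure; the nested
protocol credits a master when any of its top three subpockets matches.

## Synthetic fixtures and the grid oracle

The generator builds four shapes with known cavities on jittered
lattices — a hollow shell with a mouth, a channel through a block, a
dimpled slab, and a convex blob (the negative control, with its
pseudo-ligand on the surface and a `shallow` flag). Defaults are chosen
once to mimic protein-like geometry: atom radius 1.7 Å (carbon), lattice
spacing 1.5 Å so that walls overlap strongly and are sealed and smooth
at probe scale (a protein interior is dense, not a single layer of
spaced spheres), cavity radius 6 Å, and a mouth whose stated width is
the *free* aperture — a "4 Å mouth" admits water (1.4 Å) and excludes
the 3 Å probe, which is the regime the two-probe pocket definition
needs. Dummy residues cycle through the 20 amino acids so chemical
features are exercised. What these fixtures do not emulate: real packing
irregularity, chemistry-correlated geometry, flexibility, crystal
contacts — so green tests certify the algorithmic contracts, not
field performance on real structures.

The independent oracle flags grid points inaccessible to a 3 Å probe but
accessible to a 1.4 Å probe, evaluated morphologically on a distance
grid: probe-center positions with clearance ≥ r are flood-filled from
the box boundary (a sealed interior void is *inside* the SES of a
rolling probe — pure distance tests would "teleport" the probe into it)
and dilated by r via an FFT ball kernel. The pocket region is inside the
large-probe envelope, outside the small-probe envelope and outside the
atoms. `cross_check` voxelizes a pocket's probe cloud on the same grid
and reports the Jaccard index against the oracle, after clipping the
cloud to the large-probe envelope: probe spheres protrude into bulk
solvent, which no pocket definition counts as pocket volume, and the
oracle region lies inside that envelope by construction. Unclipped, the
comparison measures solvent overhang rather than localization (on the
shell fixture the clipped Jaccard is ≈ 0.85 against ≈ 0.08 unclipped,
with identical pocket localization).

On an atomic shell the bumpy exterior also hosts probes at every radius,
and under the deployment parameters the exterior network percolates with
the cavity cluster through the mouth rim; the top-ranked pocket is then
the cavity plus the surface network. This mirrors the behaviour of
probe-cluster methods on real surfaces, where generated pockets spread
along concave networks and ranking, not generation, does the
discrimination.

## Numerical choices and problem sizes

* Tangency and clash tolerance 1e−3 Å; duplicate probe centers within
  tolerance are merged keeping the lexicographically smallest triplet.
* A coarse (0.5 Å) distance grid prefilters clash tests with a safety
  band of half the cell diagonal, so no valid probe is ever rejected;
  survivors get the exact test.
* Bottleneck projection coincidence tolerance 0.1 Å; the trimming plane
  is the plane through the three atom centers (the alternative — the
  plane through the tangency points — contains the same bottleneck
  triangle test and is not separately needed).
* Collinear triplets are skipped; degenerate fixtures (overlapping
  atoms beyond half a radius) are rejected at generation.
* The 50%-overlap deduplication of binding regions is applied greedily
  in (i, j) order and re-checked to a fixed point (the prescription
  does not state whether to iterate; the fixed point guarantees the
  output invariants), ties keeping the lower ligand index.
* Examples, tests and the acceptance script run shells of ~180–310
  atoms (cavity radii 4–6 Å), 12 000–21 000 probes over 17 levels, and
  forests of 100–200 trees; these sizes exercise every code path while
  a full run on one structure stays in the minutes range on one core.

## Known limitations

* Only triplet-tangent ("fixed") probes are generated; toroidal
  two-atom rolling contacts are not probe instances in this scheme, and
  no SES triangulation of the protein itself is attempted.
* The hydropathy table is a bundled binary classification
  (config-overridable); spatially resolved hydrophobicity is out of
  scope.
* PDB input takes radii from a bundled vdW table; no protonation or
  charge assignment is performed (PQR radii always win).
* The gridded volume/area estimator for very large probe clouds trades
  ~percent-level accuracy for tractability; analytic-comparison tests
  always run on the exact path.
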